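# The epistasis classification rules: inclusive thresholds, the Venn
# partition, the refined cohorts and the dominance split.

test_that("differential calls are inclusive at both thresholds", {
  rec <- make_records(c("at_boundary", "high_fc_weak_p", "down", "null"),
                      fc_tup1 = c(1.0, 2.3, -1.0, 0.4),
                      p_tup1 = c(0.01, 0.02, 0.01, 0.5))
  calls <- call_differential(rec)
  expect_setequal(calls$up$tup1, "at_boundary")
  expect_setequal(calls$down$tup1, "down")
  expect_true(all(!c("high_fc_weak_p", "null") %in%
                  c(calls$up$tup1, calls$down$tup1)))
  expect_error(call_differential(rec[0, ]), "no expression records")
})

test_that("up and down sets are disjoint per contrast", {
  set.seed(7)
  rec <- make_records(sprintf("g%03d", 1:200),
                      fc_tup1 = rnorm(200, 0, 2),
                      p_tup1 = runif(200))
  calls <- call_differential(rec)
  for (cc in c("tup1", "cyc8", "double")) {
    expect_length(intersect(calls$up[[cc]], calls$down[[cc]]), 0)
  }
})

test_that("venn partition places each gene by its membership signature", {
  rec <- make_records(c("g1", "g2", "g3"),
                      fc_tup1 = c(2, 2, 0), p_tup1 = c(1e-5, 1e-5, 1),
                      fc_cyc8 = c(0, 2, 2), p_cyc8 = c(1, 1e-5, 1e-5),
                      fc_double = c(0, 2, 0), p_double = c(1, 1e-5, 1))
  part <- venn_partition(call_differential(rec))
  expect_equal(part[["tup1"]], "g1")
  expect_equal(part[["cyc8"]], "g3")
  expect_equal(part[["tup1+cyc8+double"]], "g2")
  expect_length(part[["double"]], 0)
})

test_that("venn partition is disjoint and conserves the union on random sets", {
  set.seed(42)
  for (rep in 1:20) {
    genes <- sprintf("g%02d", 1:40)
    rec <- make_records(genes,
                        fc_tup1 = sample(c(0, 2), 40, TRUE),
                        fc_cyc8 = sample(c(0, 2), 40, TRUE),
                        fc_double = sample(c(0, 2), 40, TRUE),
                        p_tup1 = 1e-5, p_cyc8 = 1e-5, p_double = 1e-5)
    calls <- call_differential(rec)
    part <- venn_partition(calls)
    regions <- unclass(part)
    all_assigned <- unlist(regions, use.names = FALSE)
    expect_equal(anyDuplicated(all_assigned), 0)
    expect_setequal(all_assigned,
                    unique(unlist(calls$up, use.names = FALSE)))
    # independent set-algebra derivation of the same partition
    oracle <- oracle_venn(calls$up$tup1, calls$up$cyc8, calls$up$double)
    for (r in names(oracle)) expect_setequal(regions[[r]], oracle[[r]])
  }
})

test_that("unique-cohort refinement applies its three filters", {
  rec <- make_records(
    c("keeps", "rises_in_double", "tup1_changed", "too_low"),
    fc_tup1 = c(0.2, 0.2, 0.5, 0.2),
    fc_cyc8 = c(2.0, 2.0, 2.0, 2.0),
    fc_double = c(1.8, 2.5, 1.8, 1.8),
    p_cyc8 = 1e-9, p_double = 1e-9,
    tpm_cyc8 = c(100, 100, 100, 50),
    tpm_double = c(80, 80, 80, 40)
  )
  part <- venn_partition(call_differential(rec))
  expect_equal(refine_unique_cohort(part, rec, "cyc8"), "keeps")
  expect_error(refine_unique_cohort(part, rec, "other"))
})

test_that("dependent cohort excludes changed or weakly expressed genes", {
  rec <- make_records(
    c("keeps", "tup1_moved", "weak"),
    fc_cyc8 = 2.0, p_cyc8 = 1e-9,
    fc_tup1 = c(0.1, -0.6, 0.1),
    tpm_tup1 = c(200, 200, 30), tpm_cyc8 = c(200, 200, 30),
    tpm_double = c(200, 200, 30)
  )
  part <- venn_partition(call_differential(rec))
  expect_equal(dependent_cohort(part, rec, "cyc8"), "keeps")
})

test_that("redundant and common cohorts return their regions verbatim", {
  rec <- make_records(
    c("dbl_only", "everywhere"),
    fc_tup1 = c(0, 2), p_tup1 = c(1, 1e-9),
    fc_cyc8 = c(0, 2), p_cyc8 = c(1, 1e-9),
    fc_double = c(2, 2), p_double = 1e-9
  )
  part <- venn_partition(call_differential(rec))
  expect_equal(redundant_cohort(part), "dbl_only")
  expect_equal(common_cohort(part), "everywhere")
  empty <- venn_partition(call_differential(
    make_records("x", fc_tup1 = 2, p_tup1 = 1e-9)))
  expect_length(redundant_cohort(empty), 0)
  expect_length(common_cohort(empty), 0)
})

test_that("dominance split distinguishes SUC2-type, FLO1-type and ties", {
  rec <- make_records(
    c("suc2ish", "flo1ish", "tie"),
    fc_tup1 = c(1.2, 3.0, 2.0),
    fc_cyc8 = c(3.0, 1.5, 2.0),
    fc_double = c(2.0, 3.5, 2.5)
  )
  split <- split_common_by_dominance(rec$gene_id, rec)
  expect_equal(unname(split["suc2ish"]), "SUC2_TYPE")
  expect_equal(unname(split["flo1ish"]), "FLO1_TYPE")
  expect_equal(unname(split["tie"]), "COMMON_OTHER")
  # the two rules are mutually exclusive on any input
  expect_length(intersect(names(split)[split == "SUC2_TYPE"],
                          names(split)[split == "FLO1_TYPE"]), 0)
  expect_error(split_common_by_dominance("absent", rec), "absent")
})

test_that("wild-type-off flag is inclusive at TPM 10", {
  rec <- make_records(c("at10", "above", "zero"),
                      tpm_wt = c(10, 10.5, 0))
  expect_setequal(flag_repressed_in_wt(rec), c("at10", "zero"))
})

test_that("refined cohorts are subsets of their regions and filters are monotone", {
  b <- synthesize_cohort_data(synthetic_spec(seed = 5, n_null = 200))
  rec <- b$expression
  part <- venn_partition(call_differential(rec))
  for (dom in c("cyc8", "tup1")) {
    region <- part[[paste0(dom, "+double")]]
    base_set <- refine_unique_cohort(part, rec, dom)
    expect_true(all(base_set %in% region))
    # raising tpm_min or lowering other_lfc_max never adds a gene
    expect_true(all(refine_unique_cohort(part, rec, dom, tpm_min = 120)
                    %in% base_set))
    expect_true(all(refine_unique_cohort(part, rec, dom,
                                         other_lfc_max = 0.1)
                    %in% base_set))
  }
  dep <- dependent_cohort(part, rec, "cyc8")
  expect_true(all(dep %in% part[["cyc8"]]))
  expect_true(all(dependent_cohort(part, rec, "cyc8", tpm_min = 150)
                  %in% dep))
})
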