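# The epistasis classification core: differential calls at the
# |log2FC| >= 1, padj <= 0.01 thresholds, the three-set Venn partition
# of upregulated genes, the refined unique/redundant/dependent cohorts,
# and the dominance split of the commonly repressed genes into
# FLO1-type and SUC2-type classes.

region_key <- function(members) paste(CONTRASTS[CONTRASTS %in% members],
                                      collapse = "+")

VENN_REGIONS <- c("tup1", "cyc8", "double",
                  "tup1+cyc8", "tup1+double", "cyc8+double",
                  "tup1+cyc8+double")

record_field <- function(records, what, which, genes = NULL) {
  v <- setNames(records[[paste0(what, "_", which)]], records$gene_id)
  if (is.null(genes)) v else {
    missing <- setdiff(genes, records$gene_id)
    if (length(missing) > 0) {
      stop("gene(s) absent from expression records: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    v[genes]
  }
}

#' Call differentially expressed genes per contrast
#'
#' A gene is called up in a contrast when `log2FC >= lfc_min` and
#' `padj <= padj_max`, and down when `log2FC <= -lfc_min` and
#' `padj <= padj_max`.  Both thresholds are inclusive, matching the
#' two-fold / 0.01 convention the analysis is built on.
#'
#' @param records Expression data.frame (see
#'   [read_expression_table()]).
#' @param lfc_min Minimum absolute log2 fold-change (default 1).
#' @param padj_max Maximum adjusted p-value (default 0.01).
#' @return An object of class `differential_calls`: lists `up` and
#'   `down` of gene-id vectors per contrast, plus the thresholds used.
#' @export
call_differential <- function(records, lfc_min = 1, padj_max = 0.01) {
  records <- validate_expression_records(records)
  if (nrow(records) == 0) stop("no expression records supplied")
  up <- list(); down <- list()
  for (cc in CONTRASTS) {
    fc <- records[[paste0("log2fc_", cc)]]
    p <- records[[paste0("padj_", cc)]]
    up[[cc]] <- records$gene_id[fc >= lfc_min & p <= padj_max]
    down[[cc]] <- records$gene_id[fc <= -lfc_min & p <= padj_max]
  }
  structure(
    list(up = up, down = down,
         thresholds = list(lfc_min = lfc_min, padj_max = padj_max)),
    class = "differential_calls"
  )
}

#' @export
print.differential_calls <- function(x, ...) {
  cat("Differential calls (|log2FC| >=", x$thresholds$lfc_min,
      ", padj <=", x$thresholds$padj_max, ")\n")
  for (cc in CONTRASTS) {
    cat(sprintf("  %-6s up %4d  down %4d\n", cc,
                length(x$up[[cc]]), length(x$down[[cc]])))
  }
  invisible(x)
}

#' Partition upregulated genes by membership signature
#'
#' Places every gene upregulated in at least one mutant into exactly
#' one of the seven non-empty regions of the three-set Venn diagram
#' over the `tup1`, `cyc8` and `double` up-sets.
#'
#' @param calls A `differential_calls` object.
#' @return An object of class `venn_partition`: a named list of
#'   gene-id vectors keyed by signature (`"tup1"`, `"cyc8+double"`,
#'   ..., `"tup1+cyc8+double"`).
#' @export
venn_partition <- function(calls) {
  stopifnot(inherits(calls, "differential_calls"))
  up <- calls$up
  all_genes <- unique(unlist(up, use.names = FALSE))
  membership <- vapply(all_genes, function(g) {
    region_key(CONTRASTS[vapply(CONTRASTS,
                                function(cc) g %in% up[[cc]], logical(1))])
  }, character(1))
  regions <- setNames(vector("list", length(VENN_REGIONS)), VENN_REGIONS)
  for (r in VENN_REGIONS) {
    regions[[r]] <- unname(all_genes[membership == r])
  }
  structure(regions, class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of upregulated genes\n")
  for (r in VENN_REGIONS) {
    cat(sprintf("  %-18s %4d\n", r, length(x[[r]])))
  }
  invisible(x)
}

#' Refine a unique-repression cohort
#'
#' Genes upregulated in one single mutant and the double mutant (but
#' not the other single mutant) are candidates for unique repression by
#' the dominant subunit.  Three more stringent filters retain a gene
#' only if (i) the other single mutant shows minimal change
#' (`log2FC <= other_lfc_max`), (ii) de-repression does not rise
#' further in the double mutant (`log2FC[double] <= log2FC[dominant]`),
#' and (iii) mean TPM over the de-repressing strains (dominant mutant
#' and double mutant) exceeds `tpm_min`.
#'
#' @param partition A `venn_partition`.
#' @param records Expression data.frame.
#' @param dominant `"cyc8"` or `"tup1"`: the subunit proposed to
#'   repress the cohort uniquely.
#' @param other_lfc_max Maximum log2FC in the other single mutant
#'   (default 0.3).
#' @param tpm_min Minimum mean TPM across the de-repressing strains
#'   (default 60; boundary excluded, i.e. TPM <= 60 is discarded).
#' @return Character vector of retained gene ids.
#' @export
refine_unique_cohort <- function(partition, records,
                                 dominant = c("cyc8", "tup1"),
                                 other_lfc_max = 0.3, tpm_min = 60) {
  dominant <- match.arg(dominant)
  stopifnot(inherits(partition, "venn_partition"))
  other <- setdiff(c("tup1", "cyc8"), dominant)
  region <- partition[[region_key(c(dominant, "double"))]]
  if (length(region) == 0) return(character(0))
  fc_other <- record_field(records, "log2fc", other, region)
  fc_dom <- record_field(records, "log2fc", dominant, region)
  fc_dbl <- record_field(records, "log2fc", "double", region)
  tpm <- (record_field(records, "tpm", dominant, region) +
          record_field(records, "tpm", "double", region)) / 2
  keep <- fc_other <= other_lfc_max & fc_dbl <= fc_dom & tpm > tpm_min
  unname(region[keep])
}

#' Redundantly repressed cohort
#'
#' Genes upregulated only in the double mutant: either subunit alone
#' suffices for repression, so de-repression requires losing both.
#'
#' @param partition A `venn_partition`.
#' @return Character vector of gene ids (the `double`-only region,
#'   verbatim).
#' @export
redundant_cohort <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  partition[["double"]]
}

#' Dependent-repression cohort
#'
#' Genes upregulated only in one single mutant (not in the double)
#' suggest that de-repression upon losing one subunit requires the
#' other subunit.  Low-expression genes (mean TPM over the three mutant
#' strains at or below `tpm_min`) are discarded, as are genes showing
#' any change in the other single mutant
#' (`|log2FC| > unchanged_lfc_max`).
#'
#' @param partition A `venn_partition`.
#' @param records Expression data.frame.
#' @param solo `"cyc8"` or `"tup1"`: the single mutant in which the
#'   genes are upregulated.
#' @param unchanged_lfc_max Maximum absolute log2FC tolerated in the
#'   other single mutant (default 0.3).
#' @param tpm_min Minimum mean TPM over the three mutant strains
#'   (default 60).
#' @return Character vector of retained gene ids.
#' @export
dependent_cohort <- function(partition, records,
                             solo = c("cyc8", "tup1"),
                             unchanged_lfc_max = 0.3, tpm_min = 60) {
  solo <- match.arg(solo)
  stopifnot(inherits(partition, "venn_partition"))
  other <- setdiff(c("tup1", "cyc8"), solo)
  region <- partition[[solo]]
  if (length(region) == 0) return(character(0))
  fc_other <- record_field(records, "log2fc", other, region)
  tpm <- (record_field(records, "tpm", "tup1", region) +
          record_field(records, "tpm", "cyc8", region) +
          record_field(records, "tpm", "double", region)) / 3
  keep <- abs(fc_other) <= unchanged_lfc_max & tpm > tpm_min
  unname(region[keep])
}

#' Commonly repressed cohort
#'
#' Genes upregulated in all three deletion mutants: the core set under
#' robust repression by the intact complex.
#'
#' @param partition A `venn_partition`.
#' @return Character vector of gene ids.
#' @export
common_cohort <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  partition[["tup1+cyc8+double"]]
}

#' Split commonly repressed genes by subunit dominance
#'
#' Within the common cohort, SUC2-type genes are those whose
#' de-repression is strictly greatest in the `cyc8` mutant and strictly
#' least in the `tup1` mutant (CYC8 dominates repression); FLO1-type
#' genes are those more de-repressed in the `tup1` mutant than in the
#' `cyc8` mutant (TUP1 dominates).  The two rules are mutually
#' exclusive by construction; everything else is `COMMON_OTHER`.
#'
#' @param genes Character vector of common-cohort gene ids.
#' @param records Expression data.frame.
#' @return Named character vector mapping gene id to `"FLO1_TYPE"`,
#'   `"SUC2_TYPE"` or `"COMMON_OTHER"`.
#' @export
split_common_by_dominance <- function(genes, records) {
  if (length(genes) == 0) return(setNames(character(0), character(0)))
  fc_t <- record_field(records, "log2fc", "tup1", genes)
  fc_c <- record_field(records, "log2fc", "cyc8", genes)
  fc_d <- record_field(records, "log2fc", "double", genes)
  if (anyNA(fc_t) || anyNA(fc_c) || anyNA(fc_d)) {
    stop("gene missing a contrast fold-change")
  }
  suc2 <- fc_c > fc_t & fc_c > fc_d & fc_t < fc_c & fc_t < fc_d
  flo1 <- !suc2 & fc_t > fc_c
  labels <- ifelse(suc2, "SUC2_TYPE", ifelse(flo1, "FLO1_TYPE", "COMMON_OTHER"))
  setNames(labels, genes)
}

#' Flag genes transcriptionally off in wild type
#'
#' @param records Expression data.frame.
#' @param tpm_off_max Wild-type mean TPM at or below which a gene is
#'   considered off (default 10, inclusive).
#' @return Character vector of flagged gene ids.
#' @export
flag_repressed_in_wt <- function(records, tpm_off_max = 10) {
  records$gene_id[records$tpm_wt <= tpm_off_max]
}

#' Classify genes into Tup1-Cyc8 epistasis cohorts
#'
#' The package's central classifier.  Runs the differential calls, the
#' Venn partition of upregulated genes, the refined unique cohorts for
#' each subunit, the redundant and CYC8-repressed/TUP1-dependent
#' cohorts, the common cohort and its dominance split, and the
#' wild-type-off flag, returning everything as one classed object.
#'
#' @param records Expression data.frame (see
#'   [read_expression_table()]).
#' @param lfc_min,padj_max Differential-call thresholds (default 1 and
#'   0.01).
#' @param other_lfc_max Fold-change cut-off for "minimal change in the
#'   other mutant" (default 0.3).
#' @param tpm_min TPM floor for the refined cohorts (default 60).
#' @param tpm_off_max Wild-type "off" TPM ceiling (default 10).
#' @return An object of class `cohort_classification` with components
#'   `calls`, `partition`, `cohorts` (named list of gene-id vectors
#'   over the labels `UNIQUE_CYC8`, `UNIQUE_TUP1`, `REDUNDANT`,
#'   `CYC8_REP_TUP1_DEP`, `COMMON`, `FLO1_TYPE`, `SUC2_TYPE`,
#'   `COMMON_OTHER`, `WT_OFF`) and `thresholds`.
#' @seealso [compare_to_truth()] to score recovery on synthetic data.
#' @export
classify_cohorts <- function(records, lfc_min = 1, padj_max = 0.01,
                             other_lfc_max = 0.3, tpm_min = 60,
                             tpm_off_max = 10) {
  calls <- call_differential(records, lfc_min, padj_max)
  partition <- venn_partition(calls)
  common <- common_cohort(partition)
  split <- split_common_by_dominance(common, records)
  cohorts <- list(
    UNIQUE_CYC8 = refine_unique_cohort(partition, records, "cyc8",
                                       other_lfc_max, tpm_min),
    UNIQUE_TUP1 = refine_unique_cohort(partition, records, "tup1",
                                       other_lfc_max, tpm_min),
    REDUNDANT = redundant_cohort(partition),
    CYC8_REP_TUP1_DEP = dependent_cohort(partition, records, "cyc8",
                                         other_lfc_max, tpm_min),
    COMMON = common,
    FLO1_TYPE = names(split)[split == "FLO1_TYPE"],
    SUC2_TYPE = names(split)[split == "SUC2_TYPE"],
    COMMON_OTHER = names(split)[split == "COMMON_OTHER"],
    WT_OFF = flag_repressed_in_wt(records, tpm_off_max)
  )
  structure(
    list(calls = calls, partition = partition, cohorts = cohorts,
         n_genes = nrow(records),
         thresholds = list(lfc_min = lfc_min, padj_max = padj_max,
                           other_lfc_max = other_lfc_max,
                           tpm_min = tpm_min, tpm_off_max = tpm_off_max)),
    class = "cohort_classification"
  )
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat("Tup1-Cyc8 epistasis cohort classification\n")
  cat(sprintf("  %d genes; thresholds |log2FC| >= %g, padj <= %g\n",
              x$n_genes, x$thresholds$lfc_min, x$thresholds$padj_max))
  for (lab in names(x$cohorts)) {
    cat(sprintf("  %-18s %4d\n", lab, length(x$cohorts[[lab]])))
  }
  invisible(x)
}

#' @export
summary.cohort_classification <- function(object, ...) {
  up <- vapply(object$calls$up, length, integer(1))
  down <- vapply(object$calls$down, length, integer(1))
  regions <- vapply(unclass(object$partition), length, integer(1))
  cohorts <- vapply(object$cohorts, length, integer(1))
  structure(
    list(n_genes = object$n_genes, up = up, down = down,
         venn_regions = regions, cohort_sizes = cohorts,
         thresholds = object$thresholds),
    class = "summary.cohort_classification"
  )
}

#' @export
print.summary.cohort_classification <- function(x, ...) {
  cat("Differential genes per contrast (up / down):\n")
  for (cc in CONTRASTS) {
    cat(sprintf("  %-6s %4d / %4d\n", cc, x$up[[cc]], x$down[[cc]]))
  }
  cat("Venn regions of upregulated genes:\n")
  for (r in names(x$venn_regions)) {
    cat(sprintf("  %-18s %4d\n", r, x$venn_regions[[r]]))
  }
  cat("Cohort sizes:\n")
  for (lab in names(x$cohort_sizes)) {
    cat(sprintf("  %-18s %4d\n", lab, x$cohort_sizes[[lab]]))
  }
  invisible(x)
}

#' @describeIn classify_cohorts One row per classified gene with its
#'   primary cohort label and the wild-type-off flag.
#' @param x A `cohort_classification`.
#' @param row.names,optional,... Passed over from the generic
#'   (unused).
#' @export
as.data.frame.cohort_classification <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  primary <- c("UNIQUE_CYC8", "UNIQUE_TUP1", "REDUNDANT",
               "CYC8_REP_TUP1_DEP", "FLO1_TYPE", "SUC2_TYPE",
               "COMMON_OTHER")
  rows <- do.call(rbind, lapply(primary, function(lab) {
    g <- x$cohorts[[lab]]
    if (length(g) == 0) return(NULL)
    data.frame(gene_id = g, label = lab, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(gene_id = character(0), label = character(0))
  }
  rows$wt_off <- rows$gene_id %in% x$cohorts$WT_OFF
  rows[order(rows$gene_id), , drop = FALSE]
}
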