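# Intergenic lengths, IUPAC motif scanning and the presence-based
# enrichment rule.

test_that("intergenic lengths are strand-aware gap arithmetic", {
  lens <- c(chrI = 20000)
  genes <- data.frame(
    gene_id = c("A", "B"),
    chrom = "chrI", start = c(1000, 5000), end = c(2000, 6000),
    strand = "+", biotype = "protein_coding", stringsAsFactors = FALSE
  )
  out <- intergenic_lengths(genes, lens)
  expect_equal(out$upstream_bp[out$gene_id == "B"], 3000)
  expect_equal(out$downstream_bp[out$gene_id == "B"], 14000)  # to chrom end
  expect_equal(out$upstream_bp[out$gene_id == "A"], 1000)     # to chrom start
  expect_equal(out$orf_bp, c(1000, 1000))

  # minus-strand gene: the 5' side is the right-hand side
  genes2 <- data.frame(
    gene_id = c("B", "C"),
    chrom = "chrI", start = c(5000, 9000), end = c(6000, 9500),
    strand = c("-", "+"), biotype = "protein_coding",
    stringsAsFactors = FALSE
  )
  out2 <- intergenic_lengths(genes2, lens)
  expect_equal(out2$upstream_bp[out2$gene_id == "B"], 3000)
})

test_that("overlapping neighbours give length 0 with a warning", {
  lens <- c(chrI = 20000)
  genes <- data.frame(
    gene_id = c("A", "B"),
    chrom = "chrI", start = c(1000, 1500), end = c(2000, 2500),
    strand = "+", biotype = "protein_coding", stringsAsFactors = FALSE
  )
  expect_warning(out <- intergenic_lengths(genes, lens), "overlap")
  expect_equal(out$downstream_bp[out$gene_id == "A"], 0)
  expect_equal(out$upstream_bp[out$gene_id == "B"], 0)
})

test_that("intergenic lengths match a quadratic nearest-neighbour oracle", {
  set.seed(71)
  for (rep in 1:10) {
    n <- 6
    starts <- sort(sample(seq(0, 48000, by = 100), n)) +
      sample(0:50, n)
    widths <- sample(500:1500, n)
    genes <- data.frame(
      gene_id = sprintf("g%d", 1:n),
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      start = starts, end = starts + widths,
      strand = sample(c("+", "-"), n, replace = TRUE),
      biotype = sample(c("protein_coding", "ncRNA"), n, replace = TRUE,
                       prob = c(0.8, 0.2)),
      stringsAsFactors = FALSE
    )
    genes <- genes[sample(n), ]  # shuffled input order
    lens <- c(c1 = 60000, c2 = 60000)
    out <- suppressWarnings(intergenic_lengths(genes, lens))
    oracle <- suppressWarnings(oracle_intergenic(genes, lens))
    expect_equal(out$upstream_bp, oracle$upstream_bp)
    expect_equal(out$downstream_bp, oracle$downstream_bp)
  }
})

test_that("motif counting handles overlap, IUPAC codes and both strands", {
  # ATG twice on the forward strand; revcomp CAT absent
  expect_equal(count_motif("ATGATG", "ATG"), 2)
  expect_equal(count_motif("ATGATG", "ATG", both_strands = FALSE), 2)
  # R = A/G: GAT and AAT both match RAT (revcomp ATY adds nothing)
  expect_equal(count_motif("GATAAT", "RAT", both_strands = FALSE), 2)
  # overlapping occurrences all count
  expect_equal(count_motif("AAAA", "AA", both_strands = FALSE), 3)
  # sequence N is matched only by motif N
  expect_equal(count_motif("ANT", "AAT", both_strands = FALSE), 0)
  expect_equal(count_motif("ANT", "ANT", both_strands = FALSE), 1)
  # motif longer than sequence
  expect_equal(count_motif("ACG", "ACGT"), 0)
})

test_that("motif counts equal a naive position-wise scan", {
  set.seed(83)
  for (rep in 1:200) {
    seq <- random_dna(sample(30:80, 1), n_prob = 0.02)
    motif <- random_iupac_motif(sample(3:8, 1))
    expect_equal(count_motif(seq, motif, both_strands = FALSE),
                 oracle_count_motif(seq, motif, both_strands = FALSE))
    expect_equal(count_motif(seq, motif, both_strands = TRUE),
                 oracle_count_motif(seq, motif, both_strands = TRUE))
  }
})

test_that("two-strand counting is reverse-complement symmetric", {
  set.seed(89)
  for (rep in 1:50) {
    seq <- random_dna(60)
    motif <- random_iupac_motif(5)
    rc_seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    expect_equal(count_motif(seq, motif), count_motif(rc_seq, motif))
  }
})

test_that("count matrix agrees with per-sequence counting", {
  set.seed(97)
  seqs <- setNames(vapply(1:5, function(i) random_dna(100), ""),
                   paste0("g", 1:5))
  motifs <- data.frame(name = c("m1", "m2"),
                       consensus = c("ACGT", "RRT"))
  mat <- count_motif_matrix(seqs, motifs)
  for (i in 1:2) {
    for (g in names(seqs)) {
      expect_equal(mat[i, g],
                   count_motif(seqs[[g]], motifs$consensus[i]))
    }
  }
})

test_that("presence enrichment applies the 40% omission and 10-point rules", {
  counts <- rbind(
    strong = c(rep(1, 8), rep(0, 2), rep(1, 5), rep(0, 5)),  # 0.8 vs 0.5
    rare = c(rep(1, 3), rep(0, 7), rep(1, 3), rep(0, 7)),    # 0.3 vs 0.3
    close = c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 5))    # 0.5 vs 0.5
  )
  colnames(counts) <- paste0("g", 1:20)
  a <- paste0("g", 1:10); b <- paste0("g", 11:20)
  v <- motif_presence_enrichment(counts, a, b)
  expect_equal(v$verdict[v$motif == "strong"], "enriched_in_a")
  expect_equal(v$verdict[v$motif == "rare"], "omitted")
  expect_equal(v$verdict[v$motif == "close"], "not_different")
  expect_error(motif_presence_enrichment(counts, character(0), b), "empty")
  expect_error(motif_presence_enrichment(counts, a, c(a[1], b)), "disjoint")
})

test_that("enrichment verdicts are antisymmetric under cohort swap", {
  set.seed(103)
  counts <- matrix(rpois(5 * 40, 0.6), nrow = 5,
                   dimnames = list(paste0("m", 1:5), paste0("g", 1:40)))
  a <- paste0("g", 1:20); b <- paste0("g", 21:40)
  v1 <- motif_presence_enrichment(counts, a, b)
  v2 <- motif_presence_enrichment(counts, b, a)
  swap <- c(enriched_in_a = "enriched_in_b",
            enriched_in_b = "enriched_in_a",
            omitted = "omitted", not_different = "not_different")
  expect_equal(v2$verdict, unname(swap[v1$verdict]))
  expect_equal(v2$presence_a, v1$presence_b)
})

test_that("mean motif load averages total occurrences over a cohort", {
  counts <- rbind(m1 = c(g1 = 1, g2 = 3), m2 = c(1, 1))
  expect_equal(mean_motif_load(counts, c("g1", "g2")), 3.0)
  expect_equal(mean_motif_load(counts, "g2"), 4.0)
  expect_error(mean_motif_load(counts, character(0)), "empty")
})

test_that("length/fold-change correlation delegates to spearman", {
  lens_df <- data.frame(gene_id = paste0("g", 1:10),
                        upstream_bp = seq(100, 1000, by = 100),
                        downstream_bp = 100, orf_bp = 1000)
  rec <- make_records(paste0("g", 1:10),
                      fc_cyc8 = seq(0.1, 1.0, by = 0.1))
  res <- length_fc_correlation(lens_df, rec, paste0("g", 1:10), "cyc8")
  expect_equal(res$rho, 1)
  # identical lengths -> undefined correlation
  lens_df$upstream_bp <- 500
  expect_error(length_fc_correlation(lens_df, rec, paste0("g", 1:10),
                                     "cyc8"), "constant")
  expect_error(length_fc_correlation(lens_df, rec, paste0("g", 1:3),
                                     "cyc8"), "4")
})

test_that("shuffled length/FC pairing shows no significant correlation", {
  set.seed(109)
  lens_df <- data.frame(gene_id = paste0("g", 1:40),
                        upstream_bp = sample(100:5000, 40),
                        downstream_bp = 100, orf_bp = 1000)
  rec <- make_records(paste0("g", 1:40), fc_cyc8 = rnorm(40, 2))
  res <- length_fc_correlation(lens_df, rec, paste0("g", 1:40), "cyc8")
  expect_lt(abs(res$rho), 0.4)
  expect_gt(res$p, 0.05)
})
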