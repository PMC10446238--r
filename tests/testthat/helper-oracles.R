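# Independent brute-force oracles and small fixture builders used
# across the suite.  Oracles are deliberately naive re-derivations from
# first principles and share no code with the package internals.

# Quick expression-record constructor: one row per gene from compact
# per-contrast vectors.
make_records <- function(gene_id,
                         fc_tup1 = 0, fc_cyc8 = 0, fc_double = 0,
                         p_tup1 = 1, p_cyc8 = 1, p_double = 1,
                         tpm_wt = 50, tpm_tup1 = 100, tpm_cyc8 = 100,
                         tpm_double = 100) {
  data.frame(
    gene_id = gene_id,
    log2fc_tup1 = fc_tup1, padj_tup1 = p_tup1,
    log2fc_cyc8 = fc_cyc8, padj_cyc8 = p_cyc8,
    log2fc_double = fc_double, padj_double = p_double,
    tpm_wt = tpm_wt, tpm_tup1 = tpm_tup1, tpm_cyc8 = tpm_cyc8,
    tpm_double = tpm_double,
    stringsAsFactors = FALSE
  )
}

# Three-set region algebra built from setdiff/intersect only.
oracle_venn <- function(a, b, c) {
  list(
    "tup1" = setdiff(a, union(b, c)),
    "cyc8" = setdiff(b, union(a, c)),
    "double" = setdiff(c, union(a, b)),
    "tup1+cyc8" = setdiff(intersect(a, b), c),
    "tup1+double" = setdiff(intersect(a, c), b),
    "cyc8+double" = setdiff(intersect(b, c), a),
    "tup1+cyc8+double" = intersect(intersect(a, b), c)
  )
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Position-by-position IUPAC scan.  A sequence N is matched only by a
# motif N.
oracle_count_one_strand <- function(seq_chars, motif_chars) {
  L <- length(seq_chars); k <- length(motif_chars)
  if (k > L) return(0L)
  hits <- 0L
  for (i in seq_len(L - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      s <- seq_chars[i + j - 1]
      m <- motif_chars[j]
      if (s == "N") {
        if (m != "N") { ok <- FALSE; break }
      } else if (!(s %in% IUPAC_SETS[[m]])) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

oracle_count_motif <- function(sequence, motif, both_strands = TRUE) {
  sc <- strsplit(sequence, "")[[1]]
  mc <- strsplit(motif, "")[[1]]
  n <- oracle_count_one_strand(sc, mc)
  if (both_strands) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
              S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
              D = "H", H = "D", N = "N")
    rc <- rev(unname(comp[mc]))
    n <- n + oracle_count_one_strand(sc, rc)
  }
  n
}

random_iupac_motif <- function(len) {
  # mostly concrete bases with some degenerate codes, like real TF
  # consensus strings
  pool <- c(rep(c("A", "C", "G", "T"), 4), "R", "Y", "S", "W", "K",
            "M", "N")
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

random_dna <- function(len, n_prob = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, len, replace = TRUE)
  if (n_prob > 0) s[runif(len) < n_prob] <- "N"
  paste(s, collapse = "")
}

# Quadratic all-pairs nearest-neighbour scan for intergenic lengths.
oracle_intergenic <- function(genes, chrom_lengths) {
  res <- data.frame(gene_id = genes$gene_id, upstream_bp = NA_real_,
                    downstream_bp = NA_real_)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lb <- 0; rb <- chrom_lengths[[g$chrom]]
    for (k in seq_len(nrow(genes))) {
      o <- genes[k, ]
      if (k == i || o$chrom != g$chrom || o$biotype != "protein_coding") next
      if (o$end <= g$start && o$end > lb) lb <- o$end
      if (o$start >= g$end && o$start < rb) rb <- o$start
      if (o$start < g$start && o$end > g$start) lb <- g$start
      if (o$start < g$end && o$end > g$end) rb <- g$end
    }
    left <- g$start - lb; right <- rb - g$end
    if (g$strand == "+") {
      res$upstream_bp[i] <- left; res$downstream_bp[i] <- right
    } else {
      res$upstream_bp[i] <- right; res$downstream_bp[i] <- left
    }
  }
  res
}

# Naive O(n^3) average-linkage agglomeration; returns the member sets
# of every internal node and the merge heights.
oracle_average_linkage <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  cd <- d
  merges <- list(); heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        if (cd[i, j] < best_d) { best_d <- cd[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merged <- c(clusters[[i]], clusters[[j]])
    merges[[length(merges) + 1]] <- sort(merged)
    heights <- c(heights, best_d)
    # average linkage: size-weighted mean of the two old distances
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    new_d <- (ni * cd[i, ] + nj * cd[j, ]) / (ni + nj)
    keep <- setdiff(seq_along(clusters), c(i, j))
    cd <- rbind(cbind(cd[keep, keep, drop = FALSE], new_d[keep]),
                c(new_d[keep], 0))
    clusters <- c(clusters[keep], list(merged))
  }
  list(members = merges, heights = heights)
}
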