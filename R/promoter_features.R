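# Promoter-level features of the commonly repressed gene cohorts:
# strand-aware intergenic lengths, IUPAC consensus motif scanning of
# 1-kb upstream windows, and the presence-based enrichment rule (omit
# motifs below 40% presence in both cohorts; call a difference of 10
# percentage points or more enriched).

#' Strand-aware intergenic lengths
#'
#' For every gene, the gap between each of its boundaries and the
#' nearest boundary of the nearest protein-coding gene on that side
#' (regardless of the neighbour's strand).  The upstream length is the
#' gap on the gene's 5' side (left for `+` strand, right for `-`);
#' terminal genes are bounded by the chromosome end.  An overlapping
#' neighbour yields length 0 with a warning.
#'
#' @param genes Annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `biotype`).
#' @param chrom_lengths Named numeric vector.
#' @return data.frame with `gene_id`, `upstream_bp`, `downstream_bp`,
#'   `orf_bp`.
#' @export
intergenic_lengths <- function(genes, chrom_lengths) {
  validate_annotation(genes, chrom_lengths)
  n <- nrow(genes)
  left <- numeric(n); right <- numeric(n)
  overlap <- FALSE
  for (i in seq_len(n)) {
    g <- genes[i, ]
    others <- genes[genes$chrom == g$chrom &
                    genes$gene_id != g$gene_id &
                    genes$biotype == "protein_coding", , drop = FALSE]
    # left side: nearest protein-coding boundary at or before our start
    lb <- 0
    if (nrow(others) > 0) {
      ends_left <- others$end[others$end <= g$start]
      if (length(ends_left) > 0) lb <- max(ends_left)
      if (any(others$start < g$start & others$end > g$start)) {
        lb <- g$start; overlap <- TRUE
      }
    }
    left[i] <- g$start - lb
    # right side: nearest protein-coding boundary at or after our end
    rb <- chrom_lengths[[g$chrom]]
    if (nrow(others) > 0) {
      starts_right <- others$start[others$start >= g$end]
      if (length(starts_right) > 0) rb <- min(starts_right)
      if (any(others$start < g$end & others$end > g$end)) {
        rb <- g$end; overlap <- TRUE
      }
    }
    right[i] <- rb - g$end
  }
  if (overlap) warning("overlapping neighbour(s): intergenic length set to 0")
  minus <- genes$strand == "-"
  data.frame(
    gene_id = genes$gene_id,
    upstream_bp = ifelse(minus, right, left),
    downstream_bp = ifelse(minus, left, right),
    orf_bp = genes$end - genes$start,
    stringsAsFactors = FALSE
  )
}

#' Count IUPAC consensus motif occurrences in a sequence
#'
#' Counts every (possibly overlapping) position where the consensus
#' matches, plus matches of its reverse complement when both strands
#' are scanned.  IUPAC ambiguity codes in the motif are expanded
#' (R = A/G, N = any, ...); an `N` in the sequence is matched only by a
#' motif `N`.
#'
#' @param sequence DNA sequence: a character string or
#'   [Biostrings::DNAString] over A/C/G/T/N.
#' @param motif IUPAC consensus string, or a one-row motif data.frame
#'   as from [read_motifs()].
#' @param both_strands Also count reverse-complement matches (default
#'   `TRUE`).
#' @return Integer occurrence count (0 when the motif is longer than
#'   the sequence).
#' @export
count_motif <- function(sequence, motif, both_strands = TRUE) {
  if (is.data.frame(motif)) motif <- motif$consensus[1]
  subject <- if (is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(sequence))
  pat <- Biostrings::DNAString(toupper(motif))
  if (length(pat) > length(subject)) return(0L)
  n <- Biostrings::countPattern(pat, subject, fixed = "subject")
  if (both_strands) {
    n <- n + Biostrings::countPattern(Biostrings::reverseComplement(pat),
                                      subject, fixed = "subject")
  }
  as.integer(n)
}

#' Motif-by-gene occurrence count matrix
#'
#' @param sequences Named [Biostrings::DNAStringSet] (or named
#'   character vector) of promoter sequences, one per gene.
#' @param motifs Motif data.frame (`name`, `consensus`).
#' @param both_strands Scan both strands (default `TRUE`).
#' @return Integer matrix, motifs in rows, genes in columns.
#' @export
count_motif_matrix <- function(sequences, motifs, both_strands = TRUE) {
  if (!is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  counts <- matrix(0L, nrow = nrow(motifs), ncol = length(sequences),
                   dimnames = list(motifs$name, names(sequences)))
  for (i in seq_len(nrow(motifs))) {
    pat <- Biostrings::DNAString(motifs$consensus[i])
    n <- Biostrings::vcountPattern(pat, sequences, fixed = "subject")
    if (both_strands) {
      n <- n + Biostrings::vcountPattern(
        Biostrings::reverseComplement(pat), sequences, fixed = "subject")
    }
    counts[i, ] <- n
  }
  counts
}

#' Per-motif presence enrichment between two cohorts
#'
#' Presence is the fraction of a cohort's genes with at least one
#' occurrence.  A motif present in less than `presence_min` of both
#' cohorts is omitted; otherwise a difference of at least `diff_min`
#' (in proportion points) is called enriched toward the cohort with the
#' higher presence, and anything smaller is not different.
#'
#' @param counts Motif-by-gene count matrix
#'   ([count_motif_matrix()]).
#' @param cohort_a,cohort_b Disjoint, non-empty gene-id vectors, both
#'   subsets of the matrix columns.
#' @param presence_min Omission threshold on presence (default 0.40).
#' @param diff_min Minimum presence difference for enrichment, in
#'   proportion points (default 0.10).
#' @return data.frame with `motif`, `presence_a`, `presence_b`,
#'   `verdict` (one of `"omitted"`, `"enriched_in_a"`,
#'   `"enriched_in_b"`, `"not_different"`).
#' @export
motif_presence_enrichment <- function(counts, cohort_a, cohort_b,
                                      presence_min = 0.40,
                                      diff_min = 0.10) {
  if (length(cohort_a) == 0 || length(cohort_b) == 0) {
    stop("empty cohort")
  }
  if (length(intersect(cohort_a, cohort_b)) > 0) {
    stop("cohorts must be disjoint")
  }
  missing <- setdiff(c(cohort_a, cohort_b), colnames(counts))
  if (length(missing) > 0) {
    stop("cohort gene(s) absent from count matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  pa <- rowMeans(counts[, cohort_a, drop = FALSE] >= 1)
  pb <- rowMeans(counts[, cohort_b, drop = FALSE] >= 1)
  verdict <- ifelse(
    pa < presence_min & pb < presence_min, "omitted",
    ifelse(abs(pa - pb) >= diff_min,
           ifelse(pa > pb, "enriched_in_a", "enriched_in_b"),
           "not_different")
  )
  data.frame(motif = rownames(counts), presence_a = unname(pa),
             presence_b = unname(pb), verdict = unname(verdict),
             stringsAsFactors = FALSE)
}

#' Mean total motif load of a cohort
#'
#' Mean over the cohort's genes of the total occurrence count summed
#' over all motifs.
#'
#' @param counts Motif-by-gene count matrix.
#' @param cohort Non-empty gene-id vector, subset of the columns.
#' @return Numeric mean.
#' @export
mean_motif_load <- function(counts, cohort) {
  if (length(cohort) == 0) stop("empty cohort")
  missing <- setdiff(cohort, colnames(counts))
  if (length(missing) > 0) {
    stop("cohort gene(s) absent from count matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  mean(colSums(counts[, cohort, drop = FALSE]))
}

#' Correlate upstream intergenic length with de-repression
#'
#' Spearman correlation (two-tailed, t approximation) between a
#' cohort's upstream intergenic lengths and its log2 fold-changes in a
#' chosen mutant contrast.
#'
#' @param lengths data.frame from [intergenic_lengths()].
#' @param records Expression data.frame.
#' @param cohort Gene-id vector.
#' @param contrast `"tup1"`, `"cyc8"` or `"double"`.
#' @return List with `rho` and `p` (see [spearman_cor()]).
#' @export
length_fc_correlation <- function(lengths, records, cohort, contrast) {
  contrast <- match.arg(contrast, CONTRASTS)
  idx <- match(cohort, lengths$gene_id)
  if (anyNA(idx)) {
    stop("cohort gene(s) without intergenic lengths: ",
         paste(utils::head(cohort[is.na(idx)], 5), collapse = ", "))
  }
  up <- lengths$upstream_bp[idx]
  fc <- record_field(records, "log2fc", contrast, cohort)
  if (length(up) < 4) stop("need at least 4 usable pairs")
  spearman_cor(up, fc)
}
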