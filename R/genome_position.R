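# Telomere-distance computation and positional enrichment: binned
# profiles over the first tens of kb from each chromosome end, the
# sub-telomeric / non-sub-telomeric split at 25 kb, and the fraction of
# genes inside the 5-40 kb HAST-like window.

annotation_subset <- function(gene_ids, genes) {
  idx <- match(gene_ids, genes$gene_id)
  if (anyNA(idx)) {
    stop("gene(s) absent from annotation: ",
         paste(utils::head(gene_ids[is.na(idx)], 5), collapse = ", "))
  }
  genes[idx, , drop = FALSE]
}

#' Distance from each gene to its nearest telomere
#'
#' The gene position is its ORF midpoint, `floor((start + end) / 2)`
#' (0-based half-open coordinates); the distance is to the nearer
#' chromosome end.  A start-coordinate mode is available.
#'
#' @param genes Annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, ...).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param position `"midpoint"` (default) or `"start"` (strand-aware 5'
#'   start).
#' @return Named numeric vector of distances in bp.
#' @export
telomere_distance <- function(genes, chrom_lengths,
                              position = c("midpoint", "start")) {
  position <- match.arg(position)
  unknown <- setdiff(genes$chrom, names(chrom_lengths))
  if (length(unknown) > 0) {
    stop("chromosome(s) without a known length: ",
         paste(unknown, collapse = ", "))
  }
  len <- chrom_lengths[genes$chrom]
  pos <- if (position == "midpoint") {
    floor((genes$start + genes$end) / 2)
  } else {
    ifelse(genes$strand == "-", genes$end, genes$start)
  }
  setNames(pmin(pos, len - pos), genes$gene_id)
}

#' Binned telomere-distance profile of a gene set
#'
#' Genes are assigned to half-open bins `[k*w, (k+1)*w)` of their
#' telomere distance; a gene at exactly a bin boundary falls in the
#' upper bin.  Percentages are of the full input set, so a set lying
#' entirely beyond `max_distance` shows 0% in every bin.
#'
#' @param gene_ids Character vector of genes to profile.
#' @param genes Annotation data.frame.
#' @param chrom_lengths Named numeric vector.
#' @param bin_width Bin width in bp (default 5000).
#' @param max_distance Profile extent in bp (default 50000).
#' @param position Passed to [telomere_distance()].
#' @return An object of class `bin_profile`: data.frame with
#'   `bin_start`, `bin_end`, `count`, `percent`, plus attributes
#'   `genes` (per-bin gene lists) and `n_input`.
#' @export
bin_profile <- function(gene_ids, genes, chrom_lengths,
                        bin_width = 5000, max_distance = 50000,
                        position = "midpoint") {
  if (bin_width <= 0) stop("bin_width must be positive")
  ann <- annotation_subset(gene_ids, genes)
  d <- telomere_distance(ann, chrom_lengths, position)
  n_bins <- ceiling(max_distance / bin_width)
  starts <- (seq_len(n_bins) - 1) * bin_width
  bin_idx <- floor(d / bin_width) + 1
  bin_idx[d >= max_distance] <- NA
  counts <- tabulate(as.integer(bin_idx[!is.na(bin_idx)]), nbins = n_bins)
  n <- length(gene_ids)
  profile <- data.frame(
    bin_start = starts,
    bin_end = pmin(starts + bin_width, max_distance),
    count = counts,
    percent = if (n > 0) 100 * counts / n else rep(0, n_bins)
  )
  attr(profile, "genes") <- lapply(seq_len(n_bins), function(k) {
    unname(names(d)[!is.na(bin_idx) & bin_idx == k])
  })
  attr(profile, "n_input") <- n
  class(profile) <- c("bin_profile", "data.frame")
  profile
}

#' Split a gene set at the sub-telomeric cutoff
#'
#' Strict inequality: a gene is sub-telomeric when its telomere
#' distance is `< cutoff`.
#'
#' @param gene_ids Character vector.
#' @param genes Annotation data.frame.
#' @param chrom_lengths Named numeric vector.
#' @param cutoff Sub-telomeric boundary in bp (default 25000).
#' @param position Passed to [telomere_distance()].
#' @return List with `subtelomeric` and `non_subtelomeric` gene-id
#'   vectors.
#' @export
subtelomeric_split <- function(gene_ids, genes, chrom_lengths,
                               cutoff = 25000, position = "midpoint") {
  ann <- annotation_subset(gene_ids, genes)
  d <- telomere_distance(ann, chrom_lengths, position)
  list(subtelomeric = unname(names(d)[d < cutoff]),
       non_subtelomeric = unname(names(d)[d >= cutoff]))
}

#' Fraction of a gene set inside a telomere-distance window
#'
#' Default window is the 5-40 kb band where Hda1-affected sub-telomeric
#' (HAST) domains lie; the window is half-open
#' `[window[1], window[2])`.
#'
#' @param gene_ids Character vector (non-empty).
#' @param genes Annotation data.frame.
#' @param chrom_lengths Named numeric vector.
#' @param window Numeric length-2 vector, bp (default `c(5000,
#'   40000)`).
#' @param position Passed to [telomere_distance()].
#' @return Fraction in \[0, 1\].
#' @export
window_fraction <- function(gene_ids, genes, chrom_lengths,
                            window = c(5000, 40000),
                            position = "midpoint") {
  if (length(gene_ids) == 0) stop("empty gene set")
  ann <- annotation_subset(gene_ids, genes)
  d <- telomere_distance(ann, chrom_lengths, position)
  mean(d >= window[1] & d < window[2])
}
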