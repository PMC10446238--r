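# Occupancy set algebra over ChIP peak/gene sets and the ChIP-qPCR
# relative-occupancy normalization.

#' Assign ChIP peaks to genes
#'
#' Peaks carrying a pre-assigned gene label (the default situation for
#' published ChIP-Exo sets) are passed through verbatim.  Unlabelled
#' peaks are assigned to every gene whose promoter window - by default
#' the 1 kb upstream of the strand-aware 5' gene start - contains the
#' peak midpoint.  Peaks assigned to no gene are counted and reported
#' with a message.
#'
#' @param peaks data.frame from [read_peaks()].
#' @param genes Annotation data.frame.
#' @param promoter_window Length-2 numeric, bp relative to the 5' gene
#'   start (default `c(-1000, 0)`, half-open).
#' @return Character vector of occupied gene ids (unique).
#' @export
peaks_to_genes <- function(peaks, genes, promoter_window = c(-1000, 0)) {
  assigned <- peaks$assigned_gene[!is.na(peaks$assigned_gene)]
  todo <- peaks[is.na(peaks$assigned_gene), , drop = FALSE]
  hits <- character(0)
  if (nrow(todo) > 0) {
    mid <- floor((todo$start + todo$end) / 2)
    minus <- genes$strand == "-"
    tss <- ifelse(minus, genes$end, genes$start)
    win_start <- ifelse(minus, tss - promoter_window[2], tss + promoter_window[1])
    win_end <- ifelse(minus, tss - promoter_window[1], tss + promoter_window[2])
    n_unassigned <- 0L
    for (i in seq_len(nrow(todo))) {
      in_win <- genes$chrom == todo$chrom[i] &
        mid[i] >= win_start & mid[i] < win_end
      if (!any(in_win)) n_unassigned <- n_unassigned + 1L
      hits <- c(hits, genes$gene_id[in_win])
    }
    if (n_unassigned > 0) {
      message(n_unassigned, " peak(s) fell in no promoter window")
    }
  }
  unique(c(assigned, hits))
}

#' Two-set occupancy Venn summary
#'
#' @param set_a,set_b Gene-id vectors (occupied genes for two
#'   factors).
#' @param labels Length-2 character vector naming the factors.
#' @return Object of class `occupancy_venn`: sizes, intersection and
#'   unique counts, and the gene sets themselves.
#' @export
occupancy_venn <- function(set_a, set_b, labels = c("A", "B")) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  both <- intersect(set_a, set_b)
  structure(
    list(labels = labels,
         n_a = length(set_a), n_b = length(set_b),
         n_intersect = length(both),
         unique_a = length(set_a) - length(both),
         unique_b = length(set_b) - length(both),
         genes = list(a = set_a, b = set_b, intersect = both)),
    class = "occupancy_venn"
  )
}

#' @export
print.occupancy_venn <- function(x, ...) {
  cat(sprintf("Occupancy overlap: %s (%d) vs %s (%d)\n",
              x$labels[1], x$n_a, x$labels[2], x$n_b))
  cat(sprintf("  shared %d; unique %d / %d\n",
              x$n_intersect, x$unique_a, x$unique_b))
  invisible(x)
}

#' Overlap of occupied genes with differential genes
#'
#' @param occupied Gene-id vector of occupied genes.
#' @param de_genes Non-empty gene-id vector of differentially
#'   transcribed genes (typically up and down combined for one
#'   contrast).
#' @return List with `count` (overlap size) and `fraction` (of the
#'   differential set).
#' @export
occupancy_vs_de <- function(occupied, de_genes) {
  de_genes <- unique(de_genes)
  if (length(de_genes) == 0) stop("empty differential gene set")
  count <- length(intersect(unique(occupied), de_genes))
  list(count = count, fraction = count / length(de_genes))
}

#' ChIP-qPCR relative occupancy
#'
#' The IP/input signal at the target locus normalised to the IP/input
#' signal at an internal negative-control region, optionally further
#' normalised to the relative occupancy of a reference strain (a
#' deletion or untagged strain processed the same way).
#'
#' @param target_ip,target_input IP and input signals at the target
#'   locus.
#' @param control_ip,control_input Signals at the negative-control
#'   region.
#' @param reference_relative Optional positive relative occupancy of
#'   the reference strain.
#' @return Numeric relative occupancy.
#' @export
relative_occupancy <- function(target_ip, target_input,
                               control_ip, control_input,
                               reference_relative = NULL) {
  terms <- c(target_input = target_input, control_input = control_input,
             control_ip = control_ip)
  zero <- names(terms)[terms <= 0]
  if (length(zero) > 0) {
    stop("division by zero or negative signal in: ",
         paste(zero, collapse = ", "))
  }
  r <- (target_ip / target_input) / (control_ip / control_input)
  if (!is.null(reference_relative)) {
    if (reference_relative <= 0) {
      stop("division by zero or negative signal in: reference_relative")
    }
    r <- r / reference_relative
  }
  r
}
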