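# Seeded generator for synthetic study data: an expression table with
# planted epistasis cohorts, a chromosome-arm genome with controlled
# sub-telomeric placement, promoter sequences with motifs planted at
# per-cohort frequencies, per-factor peak sets, and the ground-truth
# table the classifier must recover.

SYNTH_LABELS <- c("UNIQUE_CYC8", "UNIQUE_TUP1", "REDUNDANT",
                  "CYC8_REP_TUP1_DEP", "FLO1_TYPE", "SUC2_TYPE",
                  "COMMON_OTHER")

# Yeast-like chromosome-arm geometry (16 chromosomes, ~12 Mb total).
DEFAULT_CHROM_LENGTHS <- setNames(
  c(230218, 813184, 316620, 1531933, 576874, 270161, 1090940, 562643,
    439888, 745751, 666816, 1078177, 924431, 784333, 1091291, 948066),
  paste0("chr", c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                  "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI"))
)

# Consensus motifs for the regulators reported enriched at the two
# common-cohort classes; planted at high presence in their class.
DEFAULT_MOTIFS <- data.frame(
  name = c("NRG1", "MSN2", "HAP1", "YAP1", "HAC1", "GCN4"),
  consensus = c("CCCTC", "MAGGGG", "CGGNNNTANCGG", "TTACTAA",
                "CAGCGTG", "TGACTCA"),
  stringsAsFactors = FALSE
)

default_motif_presence <- function(motifs) {
  labels <- c(SYNTH_LABELS, "NULL")
  presence <- matrix(0.2, nrow = nrow(motifs), ncol = length(labels),
                     dimnames = list(motifs$name, labels))
  suc2_motifs <- intersect(c("NRG1", "MSN2", "HAP1"), motifs$name)
  flo1_motifs <- intersect(c("YAP1", "HAC1", "GCN4"), motifs$name)
  presence[suc2_motifs, "SUC2_TYPE"] <- 0.8
  presence[suc2_motifs, "FLO1_TYPE"] <- 0.4
  presence[flo1_motifs, "FLO1_TYPE"] <- 0.8
  presence[flo1_motifs, "SUC2_TYPE"] <- 0.4
  presence
}

#' Specification for the synthetic-data generator
#'
#' Collects every knob of the generator with defaults mirroring the
#' study conditions: cohort sizes 13 (unique CYC8), 6 (unique TUP1),
#' 131 (redundant), 14 (CYC8-repressed/TUP1-dependent) and a common
#' cohort of 429 split 40/110/279 into FLO1-type, SUC2-type and the
#' remainder; planted effects clear every classification threshold by
#' the stated margins.
#'
#' @param seed Integer RNG seed (default 17).
#' @param n_null Number of unregulated background genes (default
#'   2000).
#' @param cohort_sizes Named integer vector over the labels
#'   `UNIQUE_CYC8`, `UNIQUE_TUP1`, `REDUNDANT`, `CYC8_REP_TUP1_DEP`,
#'   `FLO1_TYPE`, `SUC2_TYPE`, `COMMON_OTHER`.
#' @param margin_lfc Minimum clearance of every log2FC threshold
#'   (default 0.5 log2 units).
#' @param margin_tpm Minimum clearance of the TPM filters (default
#'   20).
#' @param null_lfc_sd Standard deviation of null-gene fold-change
#'   noise (default 0.15).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param subtel_fraction Length-2 named numeric: probability that a
#'   cohort / null gene is placed sub-telomerically (defaults 0.6 and
#'   0.1).
#' @param subtel_cutoff Sub-telomeric boundary used for placement
#'   (default 25000 bp).
#' @param motifs Motif table (`name`, `consensus`).
#' @param motif_presence Motif-by-label matrix of planting
#'   probabilities (columns over the cohort labels plus `"NULL"`).
#' @param peak_probs Named numeric: occupancy probability for genes
#'   differential in the matching single mutant (`tup1_de`,
#'   `cyc8_de`) and for everything else (`background`).
#' @param promoter_width Promoter window length in bp (default 1000).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 17,
                           n_null = 2000,
                           cohort_sizes = c(UNIQUE_CYC8 = 13,
                                            UNIQUE_TUP1 = 6,
                                            REDUNDANT = 131,
                                            CYC8_REP_TUP1_DEP = 14,
                                            FLO1_TYPE = 40,
                                            SUC2_TYPE = 110,
                                            COMMON_OTHER = 279),
                           margin_lfc = 0.5,
                           margin_tpm = 20,
                           null_lfc_sd = 0.15,
                           chrom_lengths = DEFAULT_CHROM_LENGTHS,
                           subtel_fraction = c(cohort = 0.6, null = 0.1),
                           subtel_cutoff = 25000,
                           motifs = DEFAULT_MOTIFS,
                           motif_presence = NULL,
                           peak_probs = c(tup1_de = 0.23, cyc8_de = 0.13,
                                          background = 0.05),
                           promoter_width = 1000) {
  sizes <- setNames(rep(0L, length(SYNTH_LABELS)), SYNTH_LABELS)
  sizes[names(cohort_sizes)] <- as.integer(cohort_sizes)
  if (any(sizes < 0) || n_null < 0) stop("cohort sizes must be non-negative")
  if (margin_lfc < 0 || margin_tpm < 0) {
    stop("cohort definitions unsatisfiable: margins must be non-negative")
  }
  if (is.null(motif_presence)) motif_presence <- default_motif_presence(motifs)
  if (any(motif_presence < 0 | motif_presence > 1) ||
      any(peak_probs < 0 | peak_probs > 1) ||
      any(subtel_fraction < 0 | subtel_fraction > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (any(nchar(motifs$consensus) > promoter_width)) {
    stop("motif longer than the promoter window")
  }
  structure(
    list(seed = seed, n_null = as.integer(n_null), cohort_sizes = sizes,
         margin_lfc = margin_lfc, margin_tpm = margin_tpm,
         null_lfc_sd = null_lfc_sd, chrom_lengths = chrom_lengths,
         subtel_fraction = subtel_fraction, subtel_cutoff = subtel_cutoff,
         motifs = motifs, motif_presence = motif_presence,
         peak_probs = peak_probs, promoter_width = promoter_width),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic cohort spec: seed", x$seed, "\n")
  cat("  cohorts:", paste(sprintf("%s=%d", names(x$cohort_sizes),
                                  x$cohort_sizes), collapse = " "), "\n")
  cat("  null genes:", x$n_null,
      " margins:", x$margin_lfc, "log2 /", x$margin_tpm, "TPM\n")
  invisible(x)
}

tiny_padj <- function(n) 10^runif(n, -30, -10)

# Per-label fold-change/padj/TPM draws.  Every inequality defining a
# cohort is cleared by at least the spec margins; strict-inequality
# gaps shrink with margin_lfc so recovery degrades gracefully as the
# margin approaches zero.
draw_expression <- function(label, n, spec) {
  m <- spec$margin_lfc
  up_lo <- 1 + m                      # lowest planted "up" fold-change
  gap <- max(0.05, m / 2)             # strict-inequality separation
  tpm_hi <- function(n, mult = 1) {
    lo <- mult * (60 + spec$margin_tpm)
    runif(n, lo, lo + 300)
  }
  tpm_lo <- function(n) runif(n, 0, 10)
  z <- function(n) runif(n, -0.1, 0.1)
  out <- data.frame(
    log2fc_tup1 = numeric(n), padj_tup1 = rep(1, n),
    log2fc_cyc8 = numeric(n), padj_cyc8 = rep(1, n),
    log2fc_double = numeric(n), padj_double = rep(1, n),
    tpm_wt = runif(n, 0, 8),
    tpm_tup1 = tpm_lo(n), tpm_cyc8 = tpm_lo(n), tpm_double = tpm_lo(n)
  )
  if (label == "UNIQUE_CYC8") {
    out$log2fc_tup1 <- z(n)
    out$log2fc_cyc8 <- runif(n, up_lo + 0.5, up_lo + 3)
    out$log2fc_double <- out$log2fc_cyc8 -
      runif(n, 0, pmin(0.3, out$log2fc_cyc8 - up_lo))
    out$padj_cyc8 <- tiny_padj(n); out$padj_double <- tiny_padj(n)
    out$tpm_cyc8 <- tpm_hi(n); out$tpm_double <- tpm_hi(n)
  } else if (label == "UNIQUE_TUP1") {
    out$log2fc_cyc8 <- z(n)
    out$log2fc_tup1 <- runif(n, up_lo + 0.5, up_lo + 3)
    out$log2fc_double <- out$log2fc_tup1 -
      runif(n, 0, pmin(0.3, out$log2fc_tup1 - up_lo))
    out$padj_tup1 <- tiny_padj(n); out$padj_double <- tiny_padj(n)
    out$tpm_tup1 <- tpm_hi(n); out$tpm_double <- tpm_hi(n)
  } else if (label == "REDUNDANT") {
    out$log2fc_tup1 <- z(n); out$log2fc_cyc8 <- z(n)
    out$log2fc_double <- runif(n, up_lo, up_lo + 3)
    out$padj_double <- tiny_padj(n)
    out$tpm_double <- tpm_hi(n)
  } else if (label == "CYC8_REP_TUP1_DEP") {
    out$log2fc_cyc8 <- runif(n, up_lo, up_lo + 3)
    out$log2fc_tup1 <- z(n); out$log2fc_double <- z(n)
    out$padj_cyc8 <- tiny_padj(n)
    # TUP1 is required for transcription without CYC8: the double
    # mutant stays off, so the cyc8 strain must carry the TPM filter.
    out$tpm_cyc8 <- tpm_hi(n, mult = 3)
  } else if (label == "FLO1_TYPE") {
    out$log2fc_cyc8 <- runif(n, up_lo, up_lo + 1.5)
    out$log2fc_tup1 <- out$log2fc_cyc8 + runif(n, gap, m + 1)
    out$log2fc_double <- out$log2fc_cyc8 +
      runif(n, 0, 1) * (out$log2fc_tup1 - out$log2fc_cyc8)
    out$padj_tup1 <- tiny_padj(n); out$padj_cyc8 <- tiny_padj(n)
    out$padj_double <- tiny_padj(n)
    out$tpm_tup1 <- tpm_hi(n); out$tpm_cyc8 <- tpm_hi(n)
    out$tpm_double <- tpm_hi(n)
  } else if (label == "SUC2_TYPE") {
    out$log2fc_tup1 <- runif(n, up_lo, up_lo + 1)
    out$log2fc_double <- out$log2fc_tup1 + runif(n, gap, m + 0.5)
    out$log2fc_cyc8 <- out$log2fc_double + runif(n, gap, m + 0.5)
    out$padj_tup1 <- tiny_padj(n); out$padj_cyc8 <- tiny_padj(n)
    out$padj_double <- tiny_padj(n)
    out$tpm_tup1 <- tpm_hi(n); out$tpm_cyc8 <- tpm_hi(n)
    out$tpm_double <- tpm_hi(n)
  } else if (label == "COMMON_OTHER") {
    out$log2fc_tup1 <- runif(n, up_lo, up_lo + 1.5)
    out$log2fc_cyc8 <- out$log2fc_tup1   # exact tie: neither dominates
    out$log2fc_double <- out$log2fc_tup1 + runif(n, 0, 1)
    out$padj_tup1 <- tiny_padj(n); out$padj_cyc8 <- tiny_padj(n)
    out$padj_double <- tiny_padj(n)
    out$tpm_tup1 <- tpm_hi(n); out$tpm_cyc8 <- tpm_hi(n)
    out$tpm_double <- tpm_hi(n)
  } else {                              # NULL background
    clip <- function(v) pmax(pmin(v, 0.5), -0.5)
    out$log2fc_tup1 <- clip(rnorm(n, 0, spec$null_lfc_sd))
    out$log2fc_cyc8 <- clip(rnorm(n, 0, spec$null_lfc_sd))
    out$log2fc_double <- clip(rnorm(n, 0, spec$null_lfc_sd))
    for (s in STRAINS) {
      out[[paste0("tpm_", s)]] <- exp(rnorm(n, log(50), 1))
    }
  }
  out
}

place_genes <- function(labels, spec) {
  n <- length(labels)
  lens <- spec$chrom_lengths
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  p_sub <- ifelse(labels == "NULL", spec$subtel_fraction[["null"]],
                  spec$subtel_fraction[["cohort"]])
  subtel <- runif(n) < p_sub
  cutoff <- spec$subtel_cutoff
  width <- 1200
  d <- ifelse(subtel,
              runif(n, 2000, cutoff - 1000),
              runif(n, cutoff + 1000, lens[chrom] / 2 - 1000))
  left_arm <- runif(n) < 0.5
  mid <- round(ifelse(left_arm, d, lens[chrom] - d))
  start <- pmax(0, mid - width %/% 2)
  data.frame(
    chrom = chrom, start = start, end = start + width,
    strand = sample(c("+", "-"), n, replace = TRUE),
    subtelomeric = subtel,
    stringsAsFactors = FALSE
  )
}

#' Generate promoter sequences with planted motifs
#'
#' Emits one promoter per truth gene: i.i.d. uniform A/C/G/T background
#' of the spec's window length, with motifs planted at each label's
#' presence frequency.  Presence is realised as an exact per-cohort
#' fraction (a motif with presence 0.8 in a 40-gene cohort is planted
#' in exactly 32 of its genes, chosen at random), so the planted
#' prevalences are the study conditions themselves rather than
#' binomial draws around them; insertion position and strand are
#' uniform.  Deterministic given the spec seed.
#'
#' @param spec A `synthetic_spec`.
#' @param truth Truth data.frame (needs `gene_id` and `label`).
#' @return List with `promoters` (named [Biostrings::DNAStringSet])
#'   and `planted` (motif-by-gene 0/1 matrix of planted content).
#' @export
generate_promoters <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_spec"))
  width <- spec$promoter_width
  motifs <- spec$motifs
  with_seed(spec$seed + 1, {
    planted <- matrix(0L, nrow = nrow(motifs), ncol = nrow(truth),
                      dimnames = list(motifs$name, truth$gene_id))
    cols <- ifelse(truth$label %in% colnames(spec$motif_presence),
                   truth$label, "NULL")
    for (col in unique(cols)) {
      idx <- which(cols == col)
      for (j in seq_len(nrow(motifs))) {
        n_plant <- round(spec$motif_presence[j, col] * length(idx))
        if (n_plant > 0) {
          planted[j, idx[sample.int(length(idx), n_plant)]] <- 1L
        }
      }
    }
    seqs <- character(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      s <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
      used <- logical(width)  # keep planted instances from colliding
      for (j in which(planted[, i] == 1L)) {
        ins <- strsplit(iupac_instance(motifs$consensus[j]), "")[[1]]
        if (runif(1) < 0.5) ins <- rev(chartr("ACGT", "TGCA", ins))
        for (try in 1:200) {
          pos <- sample.int(width - length(ins) + 1, 1)
          span <- pos:(pos + length(ins) - 1)
          if (!any(used[span])) {
            s[span] <- ins
            used[span] <- TRUE
            break
          }
        }
      }
      seqs[i] <- paste(s, collapse = "")
    }
    promoters <- Biostrings::DNAStringSet(seqs)
    names(promoters) <- truth$gene_id
    list(promoters = promoters, planted = planted)
  })
}

# A concrete A/C/G/T realisation of an IUPAC consensus.
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_instance <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(ch) {
    opts <- IUPAC_EXPANSION[[ch]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

generate_peaks <- function(spec, truth, genes) {
  up_tup1 <- truth$label %in% c("UNIQUE_TUP1", "FLO1_TYPE", "SUC2_TYPE",
                                "COMMON_OTHER")
  up_cyc8 <- truth$label %in% c("UNIQUE_CYC8", "CYC8_REP_TUP1_DEP",
                                "FLO1_TYPE", "SUC2_TYPE", "COMMON_OTHER")
  pp <- spec$peak_probs
  occ_tup1 <- runif(nrow(truth)) <
    ifelse(up_tup1, pp[["tup1_de"]], pp[["background"]])
  occ_cyc8 <- runif(nrow(truth)) <
    ifelse(up_cyc8, pp[["cyc8_de"]], pp[["background"]])
  peak_df <- function(occ) {
    g <- genes[occ, , drop = FALSE]
    minus <- g$strand == "-"
    tss <- ifelse(minus, g$end, g$start)
    start <- pmax(0, ifelse(minus, tss + 100, tss - 300))
    data.frame(chrom = g$chrom, start = start, end = start + 200,
               assigned_gene = g$gene_id, stringsAsFactors = FALSE)
  }
  list(tup1 = peak_df(occ_tup1), cyc8 = peak_df(occ_cyc8),
       occupied = list(tup1 = occ_tup1, cyc8 = occ_cyc8))
}

#' Generate a full synthetic study bundle
#'
#' Draws, deterministically for the spec seed, an expression table with
#' the planted cohorts, gene annotation on the synthetic chromosomes,
#' promoter sequences, per-factor peak sets and the ground-truth table.
#' Running [classify_cohorts()] on the expression table recovers every
#' planted label when the margins are at their defaults.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `synthetic_bundle`: list with `expression`,
#'   `genes`, `chrom_lengths`, `promoters`, `planted_motifs`,
#'   `motifs`, `peaks` (list `tup1`/`cyc8`), `truth` and `spec`.
#' @export
synthesize_cohort_data <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  labels <- c(rep(names(spec$cohort_sizes), spec$cohort_sizes),
              rep("NULL", spec$n_null))
  with_seed(spec$seed, {
    labels <- sample(labels)
    n <- length(labels)
    gene_id <- sprintf("SYN%04d", seq_len(n))
    expr_parts <- lapply(unique(labels), function(lab) {
      idx <- which(labels == lab)
      cbind(gene_id = gene_id[idx], draw_expression(lab, length(idx), spec))
    })
    expression <- do.call(rbind, expr_parts)
    expression <- expression[order(match(expression$gene_id, gene_id)), ]
    rownames(expression) <- NULL
    placement <- place_genes(labels, spec)
    genes <- data.frame(
      gene_id = gene_id, chrom = placement$chrom,
      start = placement$start, end = placement$end,
      strand = placement$strand, biotype = "protein_coding",
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      gene_id = gene_id, label = labels,
      subtelomeric = placement$subtelomeric,
      wt_off = expression$tpm_wt <= 10,
      stringsAsFactors = FALSE
    )
    peaks <- generate_peaks(spec, truth, genes)
    truth$occupied_tup1 <- peaks$occupied$tup1
    truth$occupied_cyc8 <- peaks$occupied$cyc8
    prom <- generate_promoters(spec, truth)
    truth$planted_motifs <- vapply(seq_len(n), function(i) {
      paste(rownames(prom$planted)[prom$planted[, i] == 1], collapse = ";")
    }, character(1))
    structure(
      list(expression = validate_expression_records(expression),
           genes = genes, chrom_lengths = spec$chrom_lengths,
           promoters = prom$promoters, planted_motifs = prom$planted,
           motifs = spec$motifs,
           peaks = peaks[c("tup1", "cyc8")],
           truth = truth, spec = spec),
      class = "synthetic_bundle"
    )
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic study bundle:", nrow(x$truth), "genes ( seed",
      x$spec$seed, ")\n")
  print(table(x$truth$label))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Emits the expression TSV, a GFF3 annotation with `##sequence-region`
#' pragmas, a chromosome-lengths TSV, the promoter FASTA, the motif
#' TSV, one peaks BED per factor, and the truth TSV.  Output is
#' byte-identical across runs for the same spec.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "annotation.gff3"),
    chrom_lengths = file.path(dir, "chrom_lengths.tsv"),
    promoters = file.path(dir, "promoters.fasta"),
    motifs = file.path(dir, "motifs.tsv"),
    peaks_tup1 = file.path(dir, "peaks_tup1.bed"),
    peaks_cyc8 = file.path(dir, "peaks_cyc8.bed"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression_table(bundle$expression, paths[["expression"]])
  write_annotation_gff3(bundle$genes, bundle$chrom_lengths,
                        paths[["annotation"]])
  write.table(data.frame(names(bundle$chrom_lengths),
                         as.integer(bundle$chrom_lengths)),
              paths[["chrom_lengths"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  Biostrings::writeXStringSet(bundle$promoters, paths[["promoters"]])
  write.table(bundle$motifs, paths[["motifs"]], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (factor in c("tup1", "cyc8")) {
    p <- bundle$peaks[[factor]]
    bed <- data.frame(p$chrom, p$start, p$end, p$assigned_gene, 0L, "+")
    write.table(bed, paths[[paste0("peaks_", factor)]], sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write.table(bundle$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

write_annotation_gff3 <- function(genes, chrom_lengths, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$biotype <- genes$biotype
  tmp <- tempfile(fileext = ".gff3")
  rtracklayer::export(gr, tmp, format = "gff3")
  lines <- readLines(tmp)
  unlink(tmp)
  # strip the run-dependent date/source comments; inject length pragmas
  lines <- lines[!grepl("^##(date|source-version)", lines)]
  pragmas <- sprintf("##sequence-region %s 1 %d", names(chrom_lengths),
                     as.integer(chrom_lengths))
  writeLines(c(lines[1], pragmas, lines[-1]), path)
  invisible(path)
}

#' Read a truth table written by [write_synthetic_bundle()]
#'
#' @param path Truth TSV path.
#' @return data.frame with `gene_id`, `label`, flags and planted
#'   content.
#' @export
read_truth <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Score a classification against planted truth
#'
#' Derives each gene's predicted primary cohort label (genes in no
#' cohort are `"NULL"`) and compares with the planted labels.
#'
#' @param classification A `cohort_classification`.
#' @param truth Truth data.frame (`gene_id`, `label`).
#' @return List with `n_mismatch`, `mismatches` (data.frame of gene,
#'   planted and predicted label) and `n_genes`.
#' @export
compare_to_truth <- function(classification, truth) {
  stopifnot(inherits(classification, "cohort_classification"))
  pred_tab <- as.data.frame(classification)
  predicted <- setNames(rep("NULL", nrow(truth)), truth$gene_id)
  predicted[pred_tab$gene_id] <- pred_tab$label
  bad <- predicted != truth$label
  list(
    n_mismatch = sum(bad),
    mismatches = data.frame(gene_id = truth$gene_id[bad],
                            planted = truth$label[bad],
                            predicted = unname(predicted[bad]),
                            stringsAsFactors = FALSE),
    n_genes = nrow(truth)
  )
}
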