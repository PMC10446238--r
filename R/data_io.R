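# Readers and writers for the external formats the pipeline consumes:
# the expression table (TSV), gene annotation (GFF3/BED6), chromosome
# lengths (two-column TSV), IUPAC motif tables, peak calls (BED) and
# promoter FASTA.  All genomic coordinates are normalised to 0-based
# half-open on read; BED is native, GFF3 is converted.

EXPRESSION_COLUMNS <- c(
  "gene_id",
  "log2fc_tup1", "padj_tup1",
  "log2fc_cyc8", "padj_cyc8",
  "log2fc_double", "padj_double",
  "tpm_wt", "tpm_tup1", "tpm_cyc8", "tpm_double"
)

#' Read a per-gene differential-expression table
#'
#' Reads the tab-separated expression table consumed by every
#' classifier: one row per gene with a log2 fold-change and
#' Benjamini-Hochberg adjusted p-value for each deletion-mutant
#' contrast (`tup1`, `cyc8`, `double`, all versus wild type) and the
#' mean TPM of each strain.
#'
#' Missing adjusted p-values (DESeq2 emits `NA` for independence-
#' filtered genes) are imputed to 1 so that such genes can never be
#' called differential; missing fold-changes are imputed to 0.  Both
#' imputations are reported with a message.  Set `impute = FALSE` to
#' keep `NA`s (the table then fails validation if any are present).
#'
#' @param path Path to a TSV file with header columns `gene_id`,
#'   `log2fc_tup1`, `padj_tup1`, `log2fc_cyc8`, `padj_cyc8`,
#'   `log2fc_double`, `padj_double`, `tpm_wt`, `tpm_tup1`, `tpm_cyc8`,
#'   `tpm_double`.
#' @param impute Impute missing padj to 1 and missing log2FC to 0
#'   (default `TRUE`).
#' @return A `data.frame` with the columns above, one row per gene,
#'   validated (unique gene ids, padj in \[0,1\], TPM >= 0).
#' @export
read_expression_table <- function(path, impute = TRUE) {
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  missing <- setdiff(EXPRESSION_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("expression table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  raw <- raw[EXPRESSION_COLUMNS]
  if (anyDuplicated(raw$gene_id)) {
    dup <- unique(raw$gene_id[duplicated(raw$gene_id)])
    stop("duplicate gene_id in expression table: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  num_cols <- setdiff(EXPRESSION_COLUMNS, "gene_id")
  out <- data.frame(gene_id = raw$gene_id, stringsAsFactors = FALSE)
  for (col in num_cols) {
    vals <- raw[[col]]
    vals[vals %in% c("", "NA", "na", "NaN")] <- NA_character_
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column %s, row %d",
                   vals[bad[1]], col, bad[1]))
    }
    out[[col]] <- parsed
  }
  if (impute) {
    n_padj <- sum(is.na(out[paste0("padj_", CONTRASTS)]))
    n_lfc <- sum(is.na(out[paste0("log2fc_", CONTRASTS)]))
    for (cc in CONTRASTS) {
      pc <- paste0("padj_", cc)
      fc <- paste0("log2fc_", cc)
      out[[pc]][is.na(out[[pc]])] <- 1
      out[[fc]][is.na(out[[fc]])] <- 0
    }
    if (n_padj + n_lfc > 0) {
      message(sprintf("imputed %d missing padj value(s) to 1 and %d missing log2FC value(s) to 0",
                      n_padj, n_lfc))
    }
  }
  validate_expression_records(out)
}

validate_expression_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(EXPRESSION_COLUMNS, names(records))
  if (length(missing) > 0) {
    stop("expression records missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (cc in CONTRASTS) {
    p <- records[[paste0("padj_", cc)]]
    if (anyNA(p) || any(p < 0 | p > 1)) {
      stop("padj_", cc, " must be in [0, 1] with no missing values")
    }
  }
  for (s in STRAINS) {
    t <- records[[paste0("tpm_", s)]]
    if (anyNA(t) || any(t < 0)) {
      stop("tpm_", s, " must be non-negative with no missing values")
    }
  }
  records
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]; full numeric precision is kept
#' so a write/read round trip reproduces the records.
#'
#' @param records Expression `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(records, path) {
  records <- validate_expression_records(records)
  write.table(format(records, digits = 17, trim = TRUE, scientific = NA),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-lengths table
#'
#' @param path TSV with columns chromosome name and length in bp (no
#'   header).
#' @return Named numeric vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    col.names = c("chrom", "length"),
                    stringsAsFactors = FALSE)
  lens <- as.numeric(tab$length)
  if (anyNA(lens) || any(lens <= 0)) {
    stop("chromosome lengths must be positive numbers")
  }
  setNames(lens, tab$chrom)
}

# ##sequence-region pragmas carry the chromosome lengths in GFF3;
# rtracklayer does not surface them, so pull them from the raw lines.
sequence_region_lengths <- function(path) {
  lines <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (length(lines) == 0) return(NULL)
  parts <- strsplit(trimws(lines), "[ \t]+")
  setNames(
    vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
    vapply(parts, function(p) p[2], character(1))
  )
}

#' Read gene annotation from GFF3 or BED
#'
#' Feature parsing is delegated to [rtracklayer::import()].  GFF3
#' coordinates (1-based inclusive) are converted to the package-wide
#' 0-based half-open convention; BED6 is native.  Chromosome lengths
#' come from GFF3 `##sequence-region` pragmas or from a companion
#' two-column lengths file.
#'
#' @param path Annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @param lengths Optional path to a chromosome-lengths TSV, or a named
#'   numeric vector.  Required for BED; overrides GFF3 pragmas when
#'   given.
#' @return A list with `genes` (data.frame: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `biotype`) and `chrom_lengths` (named
#'   numeric).
#' @export
read_annotation <- function(path, format = c("gff3", "bed"), lengths = NULL) {
  format <- match.arg(format)
  if (is.character(lengths)) lengths <- read_chrom_lengths(lengths)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    type <- as.character(gr$type)
    if (any(type == "gene")) gr <- gr[type == "gene"]
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    biotype <- gr$biotype
    if (is.null(biotype)) biotype <- rep(NA_character_, length(gr))
    if (is.null(lengths)) lengths <- sequence_region_lengths(path)
  } else {
    ids <- gr$name
    biotype <- rep(NA_character_, length(gr))
  }
  if (is.null(ids) || anyNA(ids)) {
    stop("every gene feature needs an identifier (GFF3 ID/Name or BED name)")
  }
  if (is.null(lengths)) {
    stop("chromosome lengths not found: supply a lengths file or ",
         "##sequence-region pragmas")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand symbol: ",
         paste(unique(strand[!strand %in% c("+", "-")]), collapse = ", "))
  }
  genes <- data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = strand,
    biotype = ifelse(is.na(biotype), "protein_coding", as.character(biotype)),
    stringsAsFactors = FALSE
  )
  validate_annotation(genes, lengths)
  list(genes = genes, chrom_lengths = lengths)
}

validate_annotation <- function(genes, chrom_lengths) {
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         genes$gene_id[duplicated(genes$gene_id)][1])
  }
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    stop("gene coordinates must satisfy 0 <= start < end")
  }
  unknown <- setdiff(genes$chrom, names(chrom_lengths))
  if (length(unknown) > 0) {
    stop("chromosome(s) not in length table: ",
         paste(unknown, collapse = ", "))
  }
  over <- genes$end > chrom_lengths[genes$chrom]
  if (any(over)) {
    stop(sprintf("gene %s ends at %d, beyond chromosome %s length %d",
                 genes$gene_id[over][1], genes$end[over][1],
                 genes$chrom[over][1],
                 as.integer(chrom_lengths[genes$chrom[over][1]])))
  }
  invisible(genes)
}

#' Write gene annotation to BED6
#'
#' Internal coordinates are already the BED convention, so this is a
#' direct dump; used for round-trip checks and the synthetic bundle.
#'
#' @param genes Annotation data.frame as returned by
#'   [read_annotation()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    0L, genes$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Read a transcription-factor motif table
#'
#' @param path TSV with two columns, motif name and IUPAC consensus
#'   (a header line `name<TAB>consensus` is tolerated).
#' @return data.frame with `name` and `consensus`.
#' @export
read_motifs <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    col.names = c("name", "consensus"),
                    stringsAsFactors = FALSE)
  if (nrow(tab) > 0 && tolower(tab$name[1]) == "name") tab <- tab[-1, ]
  tab$consensus <- toupper(tab$consensus)
  for (i in seq_len(nrow(tab))) {
    chars <- strsplit(tab$consensus[i], "")[[1]]
    if (length(chars) == 0) stop("motif ", tab$name[i], " has empty consensus")
    bad <- setdiff(chars, IUPAC_CODES)
    if (length(bad) > 0) {
      stop(sprintf("motif %s contains illegal IUPAC character(s): %s",
                   tab$name[i], paste(bad, collapse = "")))
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Read peak calls from BED
#'
#' BED intervals are native 0-based half-open.  A non-empty BED name
#' field is taken as the peak's pre-assigned gene (the ChIP-Exo sets
#' used here carry gene labels); `"."` or empty means unassigned.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `assigned_gene`
#'   (NA when unassigned).
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  name <- gr$name
  if (is.null(name)) name <- rep(NA_character_, length(gr))
  name[name %in% c("", ".")] <- NA_character_
  peaks <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    assigned_gene = as.character(name),
    stringsAsFactors = FALSE
  )
  if (any(peaks$start >= peaks$end)) stop("peak with start >= end")
  peaks
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file whose headers are gene ids.
#' @return A [Biostrings::DNAStringSet], upper-cased, named by gene id.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("FASTA header collision: ",
         names(seqs)[duplicated(names(seqs))][1])
  }
  Biostrings::DNAStringSet(toupper(seqs))
}
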