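# Orchestration: run every analysis stage a config's inputs permit and
# emit one deterministic report (JSON) plus per-stage tables.

#' Read a flat key-value run configuration
#'
#' Plain-text config: one `key = value` pair per line, optional
#' `[section]` headers (flattened into the key as `section.key`),
#' `#` comments.  All thresholds default to the study values, so a
#' config listing only input paths runs the standard analysis.
#'
#' @param path Config file path.
#' @return Named list of character values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list()
  for (line in lines) {
    if (grepl("^\\[.+\\]$", line)) {
      section <- sub("^\\[(.+)\\]$", "\\1", line)
      next
    }
    if (!grepl("=", line, fixed = TRUE)) {
      stop("malformed config line: ", line)
    }
    key <- trimws(sub("=.*$", "", line))
    value <- trimws(sub("^[^=]*=", "", line))
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    out[[key]] <- value
  }
  out
}

default_thresholds <- function() {
  list(lfc_min = 1, padj_max = 0.01, other_lfc_max = 0.3, tpm_min = 60,
       tpm_off_max = 10, subtel_cutoff = 25000, bin_width = 5000,
       max_distance = 50000, hast_window = c(5000, 40000),
       presence_min = 0.40, diff_min = 0.10,
       promoter_window = c(-1000, 0))
}

config_num <- function(config, key, default) {
  if (is.null(config[[key]])) default else
    as.numeric(strsplit(config[[key]], "[, ]+")[[1]])
}

#' Run the full downstream analysis
#'
#' Executes, as the available inputs permit: cohort classification,
#' z-score matrix and cluster order for the common cohort, telomere-
#' distance profiles and the sub-telomeric split, intergenic lengths
#' and length/fold-change correlations, promoter-motif counting and
#' cohort enrichment, and occupancy/DE overlap.  Stages whose inputs
#' are missing are reported as skipped, not errors.
#'
#' @param config Named list (see [read_run_config()]) or path to a
#'   config file.  Recognised input keys: `expression` (required),
#'   `annotation`, `annotation_format`, `chrom_lengths`, `promoters`,
#'   `motifs`, `peaks_tup1`, `peaks_cyc8`; any threshold key from the
#'   defaults (`lfc_min`, `padj_max`, `other_lfc_max`, `tpm_min`,
#'   `tpm_off_max`, `subtel_cutoff`, `bin_width`, `max_distance`,
#'   `hast_window`, `presence_min`, `diff_min`, `promoter_window`);
#'   `out_dir` for the report and per-stage TSVs.
#' @return Object of class `pipeline_report` (a nested list); written
#'   as JSON plus per-cohort TSVs when `out_dir` is set.
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  if (is.null(config$expression)) stop("config must name an expression table")
  th <- default_thresholds()
  for (key in names(th)) {
    th[[key]] <- config_num(config, key, th[[key]])
  }
  report <- list(thresholds = th, stages = list())
  records <- read_expression_table(config$expression)

  cls <- classify_cohorts(records, th$lfc_min, th$padj_max,
                          th$other_lfc_max, th$tpm_min, th$tpm_off_max)
  smry <- summary(cls)
  report$stages$classify <- list(
    status = "ok",
    up = as.list(smry$up), down = as.list(smry$down),
    venn_regions = as.list(smry$venn_regions),
    cohort_sizes = as.list(smry$cohort_sizes)
  )

  common <- cls$cohorts$COMMON
  if (length(common) >= 2) {
    fc <- as.matrix(records[match(common, records$gene_id),
                            paste0("log2fc_", CONTRASTS)])
    rownames(fc) <- common
    z <- row_zscores(fc)
    ord <- cluster_order(z)
    report$stages$heatmap <- list(status = "ok", n_rows = nrow(z),
                                  first_rows = rownames(z)[utils::head(ord, 5)])
  } else {
    report$stages$heatmap <- list(status = "skipped: common cohort too small")
    z <- NULL; ord <- NULL
  }

  annotation <- NULL
  if (!is.null(config$annotation)) {
    fmt <- if (is.null(config$annotation_format)) "gff3" else
      config$annotation_format
    annotation <- read_annotation(config$annotation, fmt,
                                  lengths = config$chrom_lengths)
  }

  if (!is.null(annotation)) {
    upsets <- unique(unlist(cls$calls$up, use.names = FALSE))
    profile <- bin_profile(upsets, annotation$genes,
                           annotation$chrom_lengths,
                           th$bin_width, th$max_distance)
    split <- subtelomeric_split(upsets, annotation$genes,
                                annotation$chrom_lengths, th$subtel_cutoff)
    hast <- window_fraction(upsets, annotation$genes,
                            annotation$chrom_lengths, th$hast_window)
    report$stages$position <- list(
      status = "ok",
      n_upregulated = length(upsets),
      bin_percent = profile$percent,
      subtelomeric = length(split$subtelomeric),
      non_subtelomeric = length(split$non_subtelomeric),
      hast_window_fraction = hast
    )
    lens <- intergenic_lengths(annotation$genes, annotation$chrom_lengths)
    corr <- list()
    for (cohort_name in c("FLO1_TYPE", "SUC2_TYPE")) {
      cohort <- cls$cohorts[[cohort_name]]
      if (length(cohort) >= 4) {
        for (cc in CONTRASTS) {
          r <- length_fc_correlation(lens, records, cohort, cc)
          corr[[paste(cohort_name, cc, sep = ".")]] <-
            list(rho = r$rho, p = r$p)
        }
      }
    }
    report$stages$intergenic <- list(status = "ok",
                                     n_genes = nrow(lens),
                                     correlations = corr)
  } else {
    report$stages$position <- list(status = "skipped: no annotation")
    report$stages$intergenic <- list(status = "skipped: no annotation")
    lens <- NULL
  }

  if (!is.null(config$promoters) && !is.null(config$motifs) &&
      length(cls$cohorts$FLO1_TYPE) > 0 &&
      length(cls$cohorts$SUC2_TYPE) > 0) {
    promoters <- read_fasta(config$promoters)
    motifs <- read_motifs(config$motifs)
    counts <- count_motif_matrix(promoters, motifs)
    verdicts <- motif_presence_enrichment(counts, cls$cohorts$FLO1_TYPE,
                                          cls$cohorts$SUC2_TYPE,
                                          th$presence_min, th$diff_min)
    report$stages$motifs <- list(
      status = "ok",
      cohort_a = "FLO1_TYPE", cohort_b = "SUC2_TYPE",
      verdicts = verdicts,
      mean_load_flo1 = mean_motif_load(counts, cls$cohorts$FLO1_TYPE),
      mean_load_suc2 = mean_motif_load(counts, cls$cohorts$SUC2_TYPE)
    )
  } else {
    report$stages$motifs <- list(status = "skipped: no promoter sequences")
    verdicts <- NULL
  }

  occ <- list()
  for (factor in c("tup1", "cyc8")) {
    key <- paste0("peaks_", factor)
    if (is.null(config[[key]])) next
    peaks <- read_peaks(config[[key]])
    occupied <- if (!is.null(annotation)) {
      peaks_to_genes(peaks, annotation$genes, th$promoter_window)
    } else {
      unique(peaks$assigned_gene[!is.na(peaks$assigned_gene)])
    }
    de <- union(cls$calls$up[[factor]], cls$calls$down[[factor]])
    ov <- occupancy_vs_de(occupied, de)
    occ[[factor]] <- list(n_occupied = length(occupied),
                          n_de = length(de),
                          overlap = ov$count,
                          fraction_of_de = round(ov$fraction, 3))
    occ[[paste0(factor, "_occupied")]] <- occupied
  }
  if (!is.null(occ$tup1) && !is.null(occ$cyc8)) {
    venn <- occupancy_venn(occ$tup1_occupied, occ$cyc8_occupied,
                           c("Tup1p", "Cyc8p"))
    occ$venn <- list(n_tup1 = venn$n_a, n_cyc8 = venn$n_b,
                     shared = venn$n_intersect,
                     unique_tup1 = venn$unique_a,
                     unique_cyc8 = venn$unique_b)
  }
  occ$tup1_occupied <- NULL
  occ$cyc8_occupied <- NULL
  report$stages$occupancy <- if (length(occ) > 0) {
    c(list(status = "ok"), occ)
  } else {
    list(status = "skipped: no peak sets")
  }

  report$classification <- cls
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  for (stage in names(x$stages)) {
    cat(sprintf("  %-12s %s\n", stage, x$stages[[stage]]$status))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' JSON report (stable key order, fixed float formatting) plus one TSV
#' per cohort and the motif verdict table.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- report$classification
  for (lab in names(cls$cohorts)) {
    write.table(data.frame(gene_id = sort(cls$cohorts[[lab]])),
                file.path(dir, paste0("cohort_", lab, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (identical(report$stages$motifs$status, "ok")) {
    write.table(report$stages$motifs$verdicts,
                file.path(dir, "motif_verdicts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  json <- unclass(report)
  json$classification <- NULL
  path <- file.path(dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
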