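Package: tupcyc
Title: Cohort Classification and Downstream Analysis of Tup1-Cyc8
    Co-Repressor Mutant Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of differential-expression results from
    single and double deletion mutants of the yeast Tup1-Cyc8 global
    co-repressor complex. Classifies genes into epistasis cohorts
    (uniquely repressed, redundantly repressed, dependent, and commonly
    repressed genes split by TUP1/CYC8 dominance), computes z-score
    matrices and cluster orderings for heatmaps, telomere-distance bin
    profiles and sub-telomeric enrichment, IUPAC consensus motif scans
    of promoter windows with cohort-level presence enrichment,
    ChIP-occupancy set algebra and overlap with differential calls, and
    ChIP-qPCR relative-occupancy normalization. A seeded synthetic-data
    generator plants known cohort structure so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
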