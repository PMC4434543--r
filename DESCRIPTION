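Package: bstim
Title: Ligand-Selective Transcriptional and Chromatin Profiling of Early B
    Cell Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes shared and ligand-selective transcriptional
    responses in early B cell activation (resting vs. BCR- vs. LPS-stimulated
    cells): twofold and preferential fold-change classification of gene sets,
    strand-aware TSS-anchored metagene profiles of RNA polymerase II and
    histone marks, the promoter/body traveling-ratio statistic, promoter
    motif enrichment against an unchanged-gene background, twofold miRNA
    categorization, and CpG-island proximity of promoters.  A seeded
    synthetic-data generator emulates the statistical structure of such
    experiments so every stage is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
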