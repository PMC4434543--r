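#!/usr/bin/env Rscript
# Collect the per-step outputs into one JSON report.

library(bstim)

cls <- read_table_tsv("results/classification.tsv")
trs <- read_table_tsv("results/traveling_ratios.tsv")
tests <- read_table_tsv("results/region_score_tests.tsv")
mirna <- read_table_tsv("results/mirna_categories.tsv")
cpg <- read_table_tsv("results/cpg_proportions.tsv")

report <- list(
  set_sizes = as.list(table(cls$label)),
  traveling_ratios = trs,
  rank_sum_tests = tests,
  mirna_counts = mirna_category_counts(mirna)$counts,
  cpg_proportions = cpg)
jsonlite::write_json(report, "results/report.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("Wrote results/report.json\n")
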