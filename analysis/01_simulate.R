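#!/usr/bin/env Rscript
# Simulate the study dataset: three conditions (rest, BCR, LPS), nine
# coverage tracks, expression and miRNA tables with planted fold-change
# classes, motif-planted promoters and CpG islands.  All later steps read
# the standard files this writes under scratch/data/.

library(bstim)

cfg <- sim_config(seed = 20)
cat("Simulating", sum(cfg$n_genes), "genes:",
    paste0(names(cfg$n_genes), "=", cfg$n_genes, collapse = ", "), "\n")

ds <- generate_dataset(cfg)
files <- write_dataset(ds, "scratch/data")

cat("Wrote", length(files), "files to scratch/data/\n")
cat("Ground truth traveling ratios implied by the coverage model:\n")
print(subset(ds$truth$expected_tr,
             class %in% c("bcr_pref_up", "lps_pref_up")))
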