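#!/usr/bin/env Rscript
# CpG-island proximity of promoters: a TSS inside or within 200 bp of a
# predicted island is CpG-associated.  The study finds most promoters
# associated, with no preference between the two responses.

library(bstim)

ann <- read_annotation("scratch/data/annotation.gtf")
islands <- read_cpg_bed("scratch/data/cpg_islands.bed")
cls <- read_table_tsv("results/classification.tsv")

calls <- classify_cpg(ann, islands, max_dist = 200)
write.table(calls, "results/cpg_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pr <- set_proportions(cls[, c("gene_id", "label")], calls)
write.table(pr$proportions, "results/cpg_proportions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("CpG association by gene set:\n")
print(pr$proportions, row.names = FALSE, digits = 3)
cat("\nPairwise Fisher tests (preference between sets):\n")
print(pr$pairwise, row.names = FALSE, digits = 3)
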