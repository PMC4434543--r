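#!/usr/bin/env Rscript
# Twofold categorization of normalized miRNA reads against the resting
# state: shared, single-response and opposing-direction sets.

library(bstim)

tab <- read_table_tsv("scratch/data/mirna_normalized.tsv")
truth <- jsonlite::read_json("scratch/data/ground_truth.json")

res <- categorize_mirna(tab)
write.table(res, "results/mirna_categories.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cnt <- mirna_category_counts(res)
cat("miRNA category counts:\n"); print(cnt$counts)
cat(sprintf("Changed miRNAs: %d of %d\n", cnt$n_changed, nrow(res)))
cat(sprintf("Opposing-direction miRNAs: %d up-BCR/down-LPS, %d down-BCR/up-LPS\n",
            cnt$opposing[1], cnt$opposing[2]))
planted <- unlist(truth$mirna_category)
cat(sprintf("Agreement with planted categories: %.1f%%\n",
            100 * mean(res$category == planted[res$mirna_id])))
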