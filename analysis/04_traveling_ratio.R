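#!/usr/bin/env Rscript
# RNA Pol II traveling ratios (body +301..+2250 over promoter -300..+300)
# per gene set and condition, normalized to the resting state.  The study
# signature: BCR stimulation loads promoters without a matching body gain
# (TR/TRrest < 1, pausing), LPS drives the transition to elongation
# (TR/TRrest > 1).

library(bstim)

manifest <- jsonlite::read_json("scratch/data/manifest.json")
chrlen <- unlist(manifest$chrom_lengths)
ann <- read_annotation("scratch/data/annotation.gtf")
cls <- read_table_tsv("results/classification.tsv")
sets <- split(cls$gene_id, cls$label)
sets <- sets[intersect(c("shared_up", "bcr_pref_up", "lps_pref_up",
                         "unchanged"), names(sets))]

polII <- lapply(setNames(c("rest", "BCR", "LPS"), c("rest", "BCR", "LPS")),
                function(cond)
  read_bedgraph(sprintf("scratch/data/polII_%s.bedgraph", cond),
                total_reads = manifest$library_sizes$polII[[cond]],
                chrom_lengths = chrlen))

tab <- tr_table(polII, ann, sets)
write.table(tab, "results/traveling_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Traveling ratios (TR = body/promoter mean RPM; normalized to rest):\n")
print(tab, row.names = FALSE, digits = 3)
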