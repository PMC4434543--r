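#!/usr/bin/env Rscript
# TSS-anchored metagene profiles of Pol II, H3K4me3 (both +/-2 kb) and
# H3K27me3 (+/-4 kb) for the induced and unchanged gene sets, plus the
# +/-1 kb summed-RPM comparisons between conditions (Wilcoxon rank-sum).

library(bstim)

manifest <- jsonlite::read_json("scratch/data/manifest.json")
chrlen <- unlist(manifest$chrom_lengths)
ann <- read_annotation("scratch/data/annotation.gtf")
cls <- read_table_tsv("results/classification.tsv")
sets <- split(cls$gene_id, cls$label)
sets <- sets[intersect(c("shared_up", "bcr_pref_up", "lps_pref_up",
                         "unchanged"), names(sets))]
conds <- c("rest", "BCR", "LPS")

tracks <- list()
for (sig in c("polII", "h3k4me3", "h3k27me3")) {
  tracks[[sig]] <- lapply(setNames(conds, conds), function(cond)
    read_bedgraph(sprintf("scratch/data/%s_%s.bedgraph", sig, cond),
                  total_reads = manifest$library_sizes[[sig]][[cond]],
                  chrom_lengths = chrlen))
}

tests <- list()
for (sig in names(tracks)) {
  win <- if (sig == "h3k27me3") c(-4000L, 4000L) else c(-2000L, 2000L)
  mat <- data.frame(offset = seq.int(win[1], win[2]))
  for (set in names(sets)) {
    for (cond in conds) {
      prof <- metagene_profile(tracks[[sig]][[cond]], ann, sets[[set]],
                               window = win)
      mat[[paste(set, cond, sep = ".")]] <- prof$mean_rpm
    }
    sc <- lapply(tracks[[sig]], function(tk)
      region_scores(tk, ann, sets[[set]], window = c(-1000L, 1000L)))
    for (cmp in list(c("BCR", "rest"), c("LPS", "rest"), c("BCR", "LPS"))) {
      rs <- rank_sum_test(sc[[cmp[1]]]$score, sc[[cmp[2]]]$score)
      tests[[length(tests) + 1L]] <- data.frame(
        signal = sig, gene_set = set,
        comparison = paste(cmp, collapse = "_vs_"),
        p_value = rs$p.value)
    }
  }
  write.table(mat, sprintf("results/profiles_%s.tsv", sig), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("Wrote results/profiles_", sig, ".tsv\n", sep = "")
}
tests <- do.call(rbind, tests)
write.table(tests, "results/region_score_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\n+/-1 kb summed-RPM rank-sum tests (p < 0.05 marked *):\n")
tests$sig <- ifelse(tests$p_value < 0.05, "*", "NS")
print(tests, row.names = FALSE)
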