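# Independent oracles and small fixture builders used across the suite.

# Brute-force Wilcoxon rank-sum p-value by full enumeration of the
# C(n+m, n) equally likely rank assignments (no ties assumed).
enum_ranksum_p <- function(x, y, alternative = "two.sided") {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  all_ranks <- seq_len(n + m)
  combos <- utils::combn(n + m, n)
  u_all <- apply(combos, 2, function(ix) sum(all_ranks[ix])) -
    n * (n + 1) / 2
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Direct hypergeometric upper-tail summation (binomial coefficients).
hyper_tail_p <- function(fg_hits, fg_total, bg_hits, bg_total) {
  K <- fg_hits + bg_hits
  N <- fg_total + bg_total
  ks <- fg_hits:min(fg_total, K)
  sum(choose(K, ks) * choose(N - K, fg_total - ks)) / choose(N, fg_total)
}

# Single-chromosome track from a numeric vector of per-base counts.
make_track <- function(values, total_reads = 1e6, chrom = "chr1") {
  coverage_track(stats::setNames(list(values), chrom), total_reads)
}

# Minimal transcript table: one transcript per row.
make_annotation <- function(tss, strand, chrom = "chr1",
                            gene_id = sprintf("g%02d", seq_along(tss)),
                            start = pmin(tss, tss) - 0L, end = NULL,
                            gene_length = 3000L) {
  start <- ifelse(strand == "+", tss, tss - gene_length + 1L)
  end <- start + gene_length
  data.frame(gene_id = gene_id, tx_id = paste0(gene_id, ".t1"),
             tx_rank = 1L, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand,
             tss = as.integer(tss), stringsAsFactors = FALSE)
}

# Mirror a dataset through the origin of its chromosome: coordinates are
# flipped, strands swapped, coverage reversed.  TSS-anchored profiles must
# be invariant under this transformation.
flip_track <- function(track) {
  coverage_track(lapply(track$counts, rev), track$total_reads)
}

flip_annotation <- function(ann, chrom_length) {
  out <- ann
  out$tss <- chrom_length - 1L - ann$tss
  out$start <- chrom_length - ann$end
  out$end <- chrom_length - ann$start
  out$strand <- ifelse(ann$strand == "+", "-", "+")
  out
}

# Uniform-probability consensus PWM (prob. 0.97 at the consensus base).
consensus_pwm <- function(id, consensus) {
  bases <- strsplit(consensus, "")[[1]]
  mat <- matrix(0.01, nrow = 4, ncol = length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) mat[bases[j], j] <- 0.97
  pwm(id, mat)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
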