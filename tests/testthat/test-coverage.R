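test_that("RPM normalization follows its definition", {
  tr <- make_track(c(rep(0, 10), 10, rep(0, 9)), total_reads = 1e6)
  expect_equal(as.numeric(normalize_rpm(tr)$counts$chr1)[11], 10)
  tr2 <- make_track(c(40, 0), total_reads = 2e7)
  expect_equal(as.numeric(normalize_rpm(tr2)$counts$chr1), c(2, 0))
  expect_error(coverage_track(list(chr1 = 1:3), 0), "total_reads")
})

test_that("uniform coverage yields a flat profile", {
  ann <- make_annotation(tss = c(5000, 9000), strand = c("+", "-"))
  tr <- make_track(rep(3, 15000), total_reads = 1e6)
  prof <- metagene_profile(tr, ann, window = c(-2000, 2000))
  expect_equal(prof$mean_rpm, rep(3, 4001))
  expect_equal(prof$n_anchors, 2)
})

test_that("minus-strand windows are oriented 5' to 3'", {
  # spike 100 bp genomically upstream of a minus-strand TSS is downstream
  # of transcription, so it must appear at offset +100
  vals <- rep(0, 12000); tss <- 8000
  vals[tss - 100 + 1] <- 7                       # 0-based pos tss-100
  ann <- make_annotation(tss = tss, strand = "-")
  prof <- metagene_profile(make_track(vals), ann, window = c(-500, 500))
  expect_equal(which(prof$mean_rpm > 0) - 501, 100)
  expect_equal(max(prof$mean_rpm), 7)
})

test_that("profiles average anchors arithmetically", {
  vals <- rep(0, 20000)
  vals[4000 + 50 + 1] <- 4                       # gene 1, offset +50
  vals[12000 + 50 + 1] <- 6                      # gene 2, offset +50
  ann <- make_annotation(tss = c(4000, 12000), strand = c("+", "+"))
  prof <- metagene_profile(make_track(vals), ann, window = c(-200, 200))
  expect_equal(prof$mean_rpm[201 + 50], 5)
})

test_that("profile of a union is the anchor-weighted mean of the parts", {
  set.seed(11)
  vals <- rpois(40000, 1)
  ann <- make_annotation(tss = c(5000, 12000, 20000, 28000, 35000),
                         strand = c("+", "-", "+", "+", "-"))
  tr <- make_track(vals)
  a <- ann[1:2, ]; b <- ann[3:5, ]
  pa <- metagene_profile(tr, a, window = c(-1000, 1000))
  pb <- metagene_profile(tr, b, window = c(-1000, 1000))
  pu <- metagene_profile(tr, ann, window = c(-1000, 1000))
  expect_equal(pu$mean_rpm,
               (2 * pa$mean_rpm + 3 * pb$mean_rpm) / 5)
})

test_that("a single-anchor profile sums to the region score", {
  set.seed(12)
  vals <- rpois(12000, 2)
  ann <- make_annotation(tss = 6000, strand = "-")
  tr <- make_track(vals, total_reads = 3e6)
  prof <- metagene_profile(tr, ann, window = c(-1000, 1000))
  sc <- region_scores(tr, ann, window = c(-1000, 1000))
  expect_equal(sum(prof$mean_rpm), sc$score)
})

test_that("region scores sum inclusively and vanish off-window", {
  ann <- make_annotation(tss = 5000, strand = "+")
  flat <- make_track(rep(1, 12000), total_reads = 1e6)
  expect_equal(region_scores(flat, ann, window = c(-1000, 1000))$score,
               2001)
  spike <- rep(0, 12000); spike[5000 + 1500 + 1] <- 7
  expect_equal(region_scores(make_track(spike), ann,
                             window = c(-1000, 1000))$score, 0)
  expect_equal(region_scores(make_track(rep(0, 12000)), ann)$score, 0)
})

test_that("profiles are invariant under mirroring the genome", {
  cfg <- sim_config(seed = 8,
                    n_genes = c(shared_up = 4, unchanged = 4),
                    library_sizes = list(polII = c(rest = 5e5, BCR = 5e5,
                                                   LPS = 5e5)))
  ds <- generate_dataset(cfg, what = "coverage", signals = "polII")
  tr <- ds$tracks$polII$rest
  L <- cfg$chrom_length
  fwd <- metagene_profile(tr, ds$annotation, window = c(-1500, 1500))
  rev <- metagene_profile(flip_track(tr),
                          flip_annotation(ds$annotation, L),
                          window = c(-1500, 1500))
  expect_equal(max(abs(fwd$mean_rpm - rev$mean_rpm)), 0)
})

test_that("anchors whose window leaves the chromosome are skipped", {
  ann <- make_annotation(tss = c(300, 6000), strand = c("+", "+"))
  tr <- make_track(rep(1, 12000))
  expect_warning(prof <- metagene_profile(tr, ann,
                                          window = c(-1000, 1000)),
                 "skipped")
  expect_equal(prof$n_anchors, 1)
  expect_equal(prof$n_skipped, 1)
  expect_error(metagene_profile(tr, ann[0, ], window = c(-10, 10)),
               "empty")
})

test_that("max-Pol II anchoring recovers the dominant TSS", {
  cfg <- sim_config(seed = 13, n_genes = c(shared_up = 100),
                    n_tss_range = c(2, 3),
                    library_sizes = list(polII = c(rest = 2e7, BCR = 2e7,
                                                   LPS = 2e7)))
  ds <- generate_dataset(cfg, what = "coverage", signals = "polII")
  anchors <- select_anchors(ds$annotation,
                            anchor_mode = "max_polII_tss",
                            polII_track = ds$tracks$polII$rest)
  expect_equal(nrow(anchors), 100)
  hit <- anchors$tss == ds$genes$tss[match(anchors$gene_id,
                                           ds$genes$gene_id)]
  expect_gte(mean(hit), 0.99)
})

test_that("rank-sum p-values match enumeration and handle ties", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(rs$p.value, 0.05)
  expect_true(rs$exact)
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  # identical multisets: ties force the corrected normal approximation
  tied <- rank_sum_test(c(1, 1, 2, 3), c(1, 1, 2, 3))
  expect_false(tied$exact)
  expect_equal(tied$p.value, 1)
  set.seed(21)
  for (n in c(2, 4)) for (m in c(3, 5)) {
    pool <- sample(1:1000, n + m)   # distinct values, interleaved ranks
    x <- pool[seq_len(n)]; y <- pool[-seq_len(n)]
    for (alt in c("two.sided", "less", "greater"))
      expect_equal(rank_sum_test(x, y, alt)$p.value,
                   enum_ranksum_p(x, y, alt))
  }
  expect_error(rank_sum_test(numeric(0), 1), "empty")
})
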