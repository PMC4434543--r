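test_that("uniform coverage gives the window-length ratio exactly", {
  ann <- make_annotation(tss = 5000, strand = "+")
  for (c0 in c(1, 2.5)) {
    tr <- traveling_ratio(make_track(rep(c0, 12000)), ann)
    expect_equal(tr$tr, 1950 / 601, tolerance = 1e-12)
    expect_equal(tr$promoter_mean, 601 * c0)
    expect_equal(tr$body_mean, 1950 * c0)
  }
})

test_that("the traveling ratio is invariant to count scaling", {
  set.seed(5)
  vals <- rpois(12000, 3)
  ann <- make_annotation(tss = c(5000), strand = "-",
                         gene_length = 4000L)
  base <- traveling_ratio(make_track(vals), ann)$tr
  for (k in c(2, 10, 1000))
    expect_equal(traveling_ratio(make_track(vals * k), ann)$tr, base,
                 tolerance = 1e-12)
})

test_that("promoter-only signal gives zero, empty promoter errors", {
  vals <- rep(0, 12000); vals[5000 + (-200:200) + 1] <- 5
  ann <- make_annotation(tss = 5000, strand = "+")
  expect_equal(traveling_ratio(make_track(vals), ann)$tr, 0)
  expect_error(traveling_ratio(make_track(rep(0, 12000)), ann),
               "undefined")
})

test_that("rest normalization is a plain ratio", {
  expect_equal(normalize_tr(0.4, 0.2), 2)
  expect_equal(normalize_tr(0.7, 0.7), 1)
  expect_equal(normalize_tr(0, 0.5), 0)
  expect_error(normalize_tr(1, 0), "tr_rest")
})

test_that("adding body coverage strictly increases the ratio", {
  set.seed(6)
  vals <- rpois(12000, 2) + 1
  ann <- make_annotation(tss = 5000, strand = "+")
  t0 <- traveling_ratio(make_track(vals), ann)$tr
  vals2 <- vals; vals2[5000 + (500:1500) + 1] <- vals2[5000 + (500:1500) + 1] + 3
  expect_gt(traveling_ratio(make_track(vals2), ann)$tr, t0)
})

test_that("planted body:promoter density ratios map onto TR as predicted", {
  # deterministic expected-profile track: Gaussian promoter peak + body
  # density; the closed-form prediction sums the same analytic profile
  # directly (peak tail past +300 included)
  tss <- 6000; sd <- 150; h <- 4
  gauss <- h * exp(-((seq(0, 17999) - tss)^2) / (2 * sd^2))
  ann <- make_annotation(tss = tss, strand = "+", gene_length = 6000L)
  trs <- numeric(0)
  for (r in c(0.5, 1, 2)) {
    dens <- 0.4 * r
    vals <- gauss
    vals[tss + (301:5999) + 1] <- vals[tss + (301:5999) + 1] + dens
    got <- traveling_ratio(make_track(vals), ann)$tr
    p_exp <- sum(vals[tss + (-300:300) + 1])
    b_exp <- sum(vals[tss + (301:2250) + 1])
    expect_equal(got, b_exp / p_exp, tolerance = 1e-9)
    trs <- c(trs, got)
  }
  # doubling the body density roughly doubles TR (peak tail aside)
  expect_equal(trs[3] / trs[2], 2, tolerance = 0.05)
  expect_equal(trs[2] / trs[1], 2, tolerance = 0.05)
})

test_that("bodies truncated at the gene end are flagged and shortened", {
  ann <- make_annotation(tss = 5000, strand = "+", gene_length = 1500L)
  tr <- traveling_ratio(make_track(rep(1, 12000)), ann)
  expect_equal(tr$n_truncated, 1)
  # body now spans +301..+1499 = 1199 bases
  expect_equal(tr$body_mean, 1199)
  full <- traveling_ratio(make_track(rep(1, 12000)), ann,
                          truncate_at_gene_end = FALSE)
  expect_equal(full$body_mean, 1950)
})

test_that("tr_table normalizes every condition to rest", {
  set.seed(9)
  ann <- make_annotation(tss = c(5000, 12000), strand = c("+", "-"))
  mk <- function(mult) {
    v <- rpois(20000, 1) + 1
    v[5000 + (301:2250) + 1] <- v[5000 + (301:2250) + 1] * mult
    make_track(v)
  }
  tracks <- list(rest = mk(1), BCR = mk(1), LPS = mk(3))
  tab <- tr_table(tracks, ann, list(all = ann$gene_id))
  expect_equal(tab$tr_normalized[tab$condition == "rest"], 1)
  expect_equal(nrow(tab), 3)
  expect_error(tr_table(tracks[c("BCR", "LPS")], ann,
                        list(all = ann$gene_id)), "rest")
})
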