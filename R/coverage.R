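#' Per-base coverage track
#'
#' Container for a single ChIP-seq-like signal: per-base read counts (or
#' already-normalized values) per chromosome, plus the total number of
#' mapped reads used as the RPM denominator.
#'
#' @param counts Named list of per-chromosome values: numeric/integer
#'   vectors or [S4Vectors::Rle] objects (stored as Rle).
#' @param total_reads Total mapped reads in the library (> 0).
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(counts, total_reads) {
  if (total_reads <= 0) stop_config("total_reads must be > 0")
  if (length(counts) && is.null(names(counts)))
    stop_config("counts must be a named (per-chromosome) list")
  counts <- lapply(counts, function(x) {
    if (!methods::is(x, "Rle")) x <- S4Vectors::Rle(x)
    if (any(S4Vectors::runValue(x) < 0))
      stop_config("coverage values must be >= 0")
    x
  })
  structure(list(counts = counts, total_reads = total_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$counts), "chromosome(s),",
      format(x$total_reads, big.mark = ","), "mapped reads\n")
  for (ch in names(x$counts))
    cat("  ", ch, ": ", length(x$counts[[ch]]), " bp\n", sep = "")
  invisible(x)
}

chrom_lengths <- function(track) vapply(track$counts, length, integer(1))

.rpm_factor <- function(track) 1e6 / track$total_reads

#' Reads-per-million normalization
#'
#' Scales every per-base value by `1e6 / total_reads`.  The returned track
#' has `total_reads = 1e6` so that its values are consumed as-is.
#'
#' @param track A [coverage_track()].
#' @return A `coverage_track` holding RPM values.
#' @export
normalize_rpm <- function(track) {
  f <- .rpm_factor(track)
  out <- lapply(track$counts, function(r) r * f)
  coverage_track(out, total_reads = 1e6)
}

# Decompress a track to plain per-chromosome numeric vectors once, so that
# per-anchor window extraction is a vector slice rather than an Rle
# subsetting call (orders of magnitude faster over thousands of anchors).
.materialize <- function(track) {
  if (!is.null(track$vecs)) return(track)       # already materialized
  list(vecs = lapply(track$counts, as.numeric),
       f = .rpm_factor(track))
}

# Oriented per-bp RPM vector for offsets lo..hi around a TSS (0-based).
# Positive offsets point downstream of transcription. NULL when the window
# overruns the chromosome.
.window_vals <- function(mt, chrom, tss, strand, lo, hi) {
  r <- mt$vecs[[chrom]]
  if (is.null(r)) return(NULL)
  if (strand == "+") {
    a <- tss + lo; b <- tss + hi
  } else {
    a <- tss - hi; b <- tss - lo
  }
  if (a < 0 || b >= length(r)) return(NULL)
  v <- r[(a + 1L):(b + 1L)]
  if (strand == "-") v <- rev(v)
  v * mt$f
}

.window_sum <- function(mt, chrom, tss, strand, lo, hi) {
  r <- mt$vecs[[chrom]]
  if (is.null(r)) return(NULL)
  if (strand == "+") {
    a <- tss + lo; b <- tss + hi
  } else {
    a <- tss - hi; b <- tss - lo
  }
  if (a < 0 || b >= length(r)) return(NULL)
  sum(r[(a + 1L):(b + 1L)]) * mt$f
}

#' Anchor selection for TSS-centered analyses
#'
#' In `all_tss` mode every transcript TSS is an anchor.  In `max_polII_tss`
#' mode each gene contributes the single transcript whose promoter-proximal
#' Pol II occupancy (summed RPM over `promoter_window`) is highest.
#'
#' @param annotation Transcript table as produced by [generate_dataset()]:
#'   one row per transcript with columns `gene_id`, `tx_id`, `tx_rank`,
#'   `chrom`, `strand`, `tss` (0-based), `start`, `end`.
#' @param genes Optional character vector of gene ids to keep.
#' @param anchor_mode `"all_tss"` or `"max_polII_tss"`.
#' @param polII_track Pol II [coverage_track()]; required for
#'   `max_polII_tss`.
#' @param promoter_window Offsets used to rank TSSs, default `c(-300, 300)`.
#' @return Data frame of anchors (`gene_id`, `chrom`, `tss`, `strand`,
#'   plus the transcript `start`/`end` extent).
#' @export
select_anchors <- function(annotation, genes = NULL,
                           anchor_mode = c("all_tss", "max_polII_tss"),
                           polII_track = NULL,
                           promoter_window = c(-300L, 300L)) {
  anchor_mode <- match.arg(anchor_mode)
  ann <- annotation
  if (!is.null(genes)) ann <- ann[ann$gene_id %in% genes, , drop = FALSE]
  if (nrow(ann) == 0L) stop_config("empty gene set")
  cols <- c("gene_id", "chrom", "tss", "strand", "start", "end")
  if (anchor_mode == "all_tss")
    return(ann[, cols])
  if (is.null(polII_track))
    stop_config("max_polII_tss anchoring requires polII_track")
  mt <- .materialize(polII_track)
  occ <- vapply(seq_len(nrow(ann)), function(i) {
    s <- .window_sum(mt, ann$chrom[i], ann$tss[i], ann$strand[i],
                     promoter_window[1], promoter_window[2])
    if (is.null(s)) -Inf else s
  }, numeric(1))
  keep <- unlist(lapply(split(seq_len(nrow(ann)), ann$gene_id), function(ix) {
    ix[which.max(occ[ix])]
  }), use.names = FALSE)
  ann[sort(keep), cols]
}

#' TSS-anchored metagene profile
#'
#' Mean per-offset RPM across anchors of a gene set, with transcripts
#' oriented 5'-to-3' (minus-strand windows are reversed so positive offsets
#' always point downstream of the TSS).  Anchors whose window overruns the
#' chromosome are skipped and counted.
#'
#' @inheritParams select_anchors
#' @param track The [coverage_track()] to profile.
#' @param window Offset pair, e.g. `c(-2000, 2000)`; inclusive at both ends.
#' @return A `metagene_profile`: list with `offsets`, `mean_rpm`,
#'   `n_anchors`, `n_skipped`, `anchor_mode`, `window`.
#' @export
metagene_profile <- function(track, annotation, genes = NULL,
                             window = c(-2000L, 2000L),
                             anchor_mode = c("all_tss", "max_polII_tss"),
                             polII_track = NULL) {
  anchor_mode <- match.arg(anchor_mode)
  if (window[2] < window[1]) stop_config("invalid window")
  anchors <- select_anchors(annotation, genes, anchor_mode,
                            polII_track %||% track)
  mt <- .materialize(track)
  acc <- numeric(window[2] - window[1] + 1L)
  n_used <- 0L; n_skipped <- 0L
  for (i in seq_len(nrow(anchors))) {
    v <- .window_vals(mt, anchors$chrom[i], anchors$tss[i],
                      anchors$strand[i], window[1], window[2])
    if (is.null(v)) { n_skipped <- n_skipped + 1L; next }
    acc <- acc + v
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop_config("no usable anchors in window")
  if (n_skipped > 0L)
    warning(sprintf("%d anchor(s) skipped (window outside chromosome)",
                    n_skipped))
  structure(list(offsets = seq.int(window[1], window[2]),
                 mean_rpm = acc / n_used, n_anchors = n_used,
                 n_skipped = n_skipped, anchor_mode = anchor_mode,
                 window = window),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile: offsets ", x$window[1], "..", x$window[2], ", ",
      x$n_anchors, " anchors (", x$anchor_mode, "), ",
      x$n_skipped, " skipped\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.metagene_profile <- function(x, ...) {
  data.frame(offset = x$offsets, mean_rpm = x$mean_rpm)
}

#' Summed RPM around the TSS, per gene
#'
#' Sum of oriented per-bp RPM over `window` (inclusive) around each anchor.
#' In `all_tss` mode a gene's score is the mean of its transcripts' sums; in
#' `max_polII_tss` mode the dominant TSS's sum.  Genes whose every anchor
#' falls outside the chromosome are dropped (with a warning).
#'
#' @inheritParams metagene_profile
#' @param window Offset pair, default `c(-1000, 1000)`.
#' @return Data frame (`gene_id`, `score`), attribute `n_skipped_anchors`.
#' @export
region_scores <- function(track, annotation, genes = NULL,
                          window = c(-1000L, 1000L),
                          anchor_mode = c("all_tss", "max_polII_tss"),
                          polII_track = NULL) {
  anchor_mode <- match.arg(anchor_mode)
  anchors <- select_anchors(annotation, genes, anchor_mode,
                            polII_track %||% track)
  mt <- .materialize(track)
  sums <- vapply(seq_len(nrow(anchors)), function(i) {
    s <- .window_sum(mt, anchors$chrom[i], anchors$tss[i],
                     anchors$strand[i], window[1], window[2])
    if (is.null(s)) NA_real_ else s
  }, numeric(1))
  n_skipped <- sum(is.na(sums))
  if (n_skipped > 0L)
    warning(sprintf("%d anchor(s) skipped (window outside chromosome)",
                    n_skipped))
  per_gene <- tapply(sums, anchors$gene_id, mean, na.rm = TRUE)
  out <- data.frame(gene_id = names(per_gene),
                    score = as.numeric(per_gene),
                    stringsAsFactors = FALSE)
  out <- out[!is.nan(out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped_anchors") <- n_skipped
  out
}

#' Wilcoxon rank-sum comparison of two score sets
#'
#' Two-sample Wilcoxon/Mann-Whitney test with midranks for ties.  The
#' p-value is exact (full enumeration of rank assignments) when the combined
#' sample size is at most 12 and there are no ties, and otherwise uses the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric score vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `statistic` (Mann-Whitney U of `x`), `p.value`, and
#'   `exact` (logical).
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L) stop_config("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value, exact = exact)
}
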