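#' RNA Pol II traveling ratio of a gene set
#'
#' The traveling ratio TR = b/p contrasts promoter-proximal and gene-body
#' polymerase occupancy: p is the mean over genes of summed oriented RPM in
#' the promoter window (default offsets -300..+300, 601 bp) and b the same
#' for the body window (default +301..+2250, 1950 bp; the two windows
#' partition at +300).  Low TR indicates promoter-paused polymerase; high TR
#' indicates transition to elongation.  The ratio is taken between set-level
#' means (mean of per-gene sums, each gene averaging its transcripts), not
#' as a mean of per-gene ratios.
#'
#' @inheritParams metagene_profile
#' @param promoter_window,body_window Inclusive offset pairs.
#' @param truncate_at_gene_end If `TRUE` (default), a transcript whose body
#'   window extends past the annotated gene end has the window truncated
#'   there; the number of affected transcripts is reported.
#' @return List with `promoter_mean`, `body_mean`, `tr`, `n_genes`,
#'   `n_truncated`, `anchor_mode`, and the windows used.
#' @export
traveling_ratio <- function(track, annotation, genes = NULL,
                            promoter_window = c(-300L, 300L),
                            body_window = c(301L, 2250L),
                            anchor_mode = c("all_tss", "max_polII_tss"),
                            polII_track = NULL,
                            truncate_at_gene_end = TRUE) {
  anchor_mode <- match.arg(anchor_mode)
  if (promoter_window[2] <= promoter_window[1] ||
      body_window[2] <= body_window[1])
    stop_config("windows must be non-degenerate")
  ann <- annotation
  if (!is.null(genes)) ann <- ann[ann$gene_id %in% genes, , drop = FALSE]
  if (nrow(ann) == 0L) stop_config("empty gene set")
  anchors <- select_anchors(ann, NULL, anchor_mode, polII_track %||% track)
  mt <- .materialize(track)
  n_trunc <- 0L
  p_sum <- b_sum <- rep(NA_real_, nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]; tss <- anchors$tss[i]; st <- anchors$strand[i]
    p <- .window_sum(mt, ch, tss, st,
                     promoter_window[1], promoter_window[2])
    end_off <- if (st == "+") anchors$end[i] - 1L - tss
               else tss - anchors$start[i]
    b_hi <- body_window[2]
    if (truncate_at_gene_end && end_off < b_hi) {
      b_hi <- end_off
      n_trunc <- n_trunc + 1L
    }
    b <- if (b_hi >= body_window[1])
      .window_sum(mt, ch, tss, st, body_window[1], b_hi) else 0
    if (!is.null(p) && !is.null(b)) { p_sum[i] <- p; b_sum[i] <- b }
  }
  ok <- !is.na(p_sum)
  if (!any(ok)) stop_config("no usable anchors")
  pg <- tapply(p_sum[ok], anchors$gene_id[ok], mean)
  bg <- tapply(b_sum[ok], anchors$gene_id[ok], mean)
  promoter_mean <- mean(pg); body_mean <- mean(bg)
  if (promoter_mean <= 0)
    stop_config("traveling ratio undefined: promoter occupancy is zero")
  list(promoter_mean = promoter_mean, body_mean = body_mean,
       tr = body_mean / promoter_mean, n_genes = length(pg),
       n_truncated = n_trunc, anchor_mode = anchor_mode,
       promoter_window = promoter_window, body_window = body_window)
}

#' Normalize a traveling ratio to the resting state
#'
#' @param tr_condition,tr_rest Traveling ratios (`tr_rest` > 0).
#' @return `tr_condition / tr_rest`.
#' @export
normalize_tr <- function(tr_condition, tr_rest) {
  if (any(tr_rest <= 0)) stop_config("tr_rest must be > 0")
  tr_condition / tr_rest
}

#' Traveling-ratio table across gene sets and conditions
#'
#' Computes [traveling_ratio()] for every gene set under every condition
#' track and appends the rest-normalized ratio TR(condition)/TR(rest).
#'
#' @param tracks Named list of Pol II [coverage_track()]s; must include
#'   `"rest"`.
#' @param annotation Transcript table (see [select_anchors()]).
#' @param gene_sets Named list of gene-id vectors.
#' @param ... Passed on to [traveling_ratio()].
#' @return Data frame with one row per set x condition: `gene_set`,
#'   `condition`, `promoter_mean`, `body_mean`, `tr`, `tr_normalized`.
#' @export
tr_table <- function(tracks, annotation, gene_sets, ...) {
  if (!"rest" %in% names(tracks)) stop_config("tracks must include 'rest'")
  rows <- list()
  for (set in names(gene_sets)) {
    trs <- lapply(tracks, function(tk)
      traveling_ratio(tk, annotation, gene_sets[[set]], ...))
    for (cond in names(tracks)) {
      t <- trs[[cond]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_set = set, condition = cond,
        promoter_mean = t$promoter_mean, body_mean = t$body_mean,
        tr = t$tr,
        tr_normalized = normalize_tr(t$tr, trs[["rest"]]$tr),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
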