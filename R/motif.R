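#' Position weight matrix
#'
#' @param id Motif name.
#' @param mat 4 x L numeric matrix of per-position base probabilities, rows
#'   named A, C, G, T; each column must sum to 1 (tolerance 1e-6) and L
#'   must be at least 4.
#' @return A `pwm` object.
#' @export
pwm <- function(id, mat) {
  if (!is.matrix(mat) || nrow(mat) != 4L)
    stop_config("pwm matrix must have 4 rows (A, C, G, T)")
  if (is.null(rownames(mat))) rownames(mat) <- c("A", "C", "G", "T")
  if (!identical(rownames(mat), c("A", "C", "G", "T")))
    stop_config("pwm rows must be named A, C, G, T in order")
  if (ncol(mat) < 4L) stop_config("pwm must have length >= 4")
  if (any(abs(colSums(mat) - 1) > 1e-6))
    stop_config("pwm columns must each sum to 1")
  if (any(mat < 0)) stop_config("pwm probabilities must be >= 0")
  structure(list(id = id, mat = mat), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm ", x$id, " (length ", ncol(x$mat), "), consensus ",
      .pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

# Floored log2-odds score matrix vs. a uniform 0.25 background.
.pwm_lodds <- function(p, floor = 1e-3, background = rep(0.25, 4)) {
  log2(pmax(p$mat, floor) / background)
}

.pwm_max_score <- function(p, floor = 1e-3, background = rep(0.25, 4)) {
  sum(apply(.pwm_lodds(p, floor, background), 2, max))
}

#' Read / write a JASPAR-style PWM library
#'
#' Text format: `>ID` header followed by four lines `A [ ... ]`,
#' `C [ ... ]`, `G [ ... ]`, `T [ ... ]` of per-position counts or
#' probabilities (columns are normalized on read).
#'
#' @param path File path.
#' @return `read_pwms()`: named list of [pwm()] objects.
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop_config("no PWM records in %s", path)
  out <- list()
  for (h in heads) {
    id <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]][1]
    rows <- lapply(lines[h + 1:4], function(l) {
      parts <- strsplit(trimws(gsub("^[ACGT]\\s*\\[|\\]\\s*$", "",
                                    trimws(l))), "\\s+")[[1]]
      as.numeric(parts[nzchar(parts)])
    })
    mat <- do.call(rbind, rows)
    rownames(mat) <- c("A", "C", "G", "T")
    mat <- sweep(mat, 2, colSums(mat), "/")
    out[[id]] <- pwm(id, mat)
  }
  out
}

#' @rdname read_pwms
#' @param pwms Named list of [pwm()] objects.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$mat[b, ], digits = 6,
                                      trim = TRUE), collapse = " ")), con)
  }
  invisible(path)
}

#' Extract strand-oriented promoter sequences
#'
#' One promoter per gene, anchored at the gene's representative TSS (the
#' rank-1 transcript), spanning `window` around it; minus-strand promoters
#' are reverse-complemented so that position 1 is the most upstream base.
#' Genes whose window overruns the chromosome are skipped with a warning.
#'
#' @param annotation Transcript table (see [select_anchors()]).
#' @param genome Named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param window Inclusive offset pair, default `c(-1000, 1000)` (2001 bp).
#' @param genes Optional gene-id filter.
#' @return [Biostrings::DNAStringSet] named by gene id.
#' @export
extract_promoters <- function(annotation, genome,
                              window = c(-1000L, 1000L), genes = NULL) {
  ann <- annotation[annotation$tx_rank == 1L, , drop = FALSE]
  if (!is.null(genes)) ann <- ann[ann$gene_id %in% genes, , drop = FALSE]
  seqs <- character(0); keep <- character(0); n_skip <- 0L
  for (i in seq_len(nrow(ann))) {
    chr <- genome[[ann$chrom[i]]]
    if (is.null(chr)) { n_skip <- n_skip + 1L; next }
    tss <- ann$tss[i]
    a <- tss + window[1] + 1L; b <- tss + window[2] + 1L   # 1-based
    if (a < 1L || b > length(chr)) { n_skip <- n_skip + 1L; next }
    s <- Biostrings::subseq(chr, a, b)
    if (ann$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs <- c(seqs, as.character(s)); keep <- c(keep, ann$gene_id[i])
  }
  if (n_skip > 0L)
    warning(sprintf("%d promoter(s) skipped (outside chromosome)", n_skip))
  Biostrings::DNAStringSet(stats::setNames(seqs, keep))
}

# Integer-encode sequences for the C++ scanner: A,C,G,T -> 0..3, others -1.
.encode_lookup <- local({
  lk <- rep(-1L, 256)
  lk[utf8ToInt("A") + 1L] <- 0L; lk[utf8ToInt("a") + 1L] <- 0L
  lk[utf8ToInt("C") + 1L] <- 1L; lk[utf8ToInt("c") + 1L] <- 1L
  lk[utf8ToInt("G") + 1L] <- 2L; lk[utf8ToInt("g") + 1L] <- 2L
  lk[utf8ToInt("T") + 1L] <- 3L; lk[utf8ToInt("t") + 1L] <- 3L
  lk
})

.encode_seq <- function(s) {
  .encode_lookup[utf8ToInt(as.character(s)) + 1L]
}

#' Scan one sequence with a PWM
#'
#' Log2-odds scoring against a uniform base composition at every offset on
#' both strands; positions whose window contains an ambiguous base are
#' skipped.  A hit is any window scoring at least `score_fraction` times
#' the maximum attainable score of the motif.
#'
#' @param seq Character, [Biostrings::DNAString], or anything coercible.
#' @param pwm A [pwm()] object.
#' @param score_fraction Hit threshold as a fraction of the maximum
#'   log-odds score (default 0.8).
#' @param floor Probability floor applied before taking logs (default
#'   1e-3), so zero entries cannot produce -Inf scores.
#' @return Data frame of hits: `offset` (1-based start on the given
#'   sequence), `strand`, `score`.
#' @export
scan_promoter <- function(seq, pwm, score_fraction = 0.8, floor = 1e-3) {
  code <- .encode_seq(seq)
  lodds <- .pwm_lodds(pwm, floor)
  thr <- score_fraction * .pwm_max_score(pwm, floor)
  hits <- list()
  for (strand in c("+", "-")) {
    m <- if (strand == "+") lodds
         else lodds[4:1, rev(seq_len(ncol(lodds))), drop = FALSE]
    sc <- scan_scores_cpp(code, m)
    ok <- which(!is.na(sc) & sc >= thr)
    if (length(ok))
      hits[[strand]] <- data.frame(offset = ok, strand = strand,
                                   score = sc[ok],
                                   stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ZOOPS hit indicator per sequence for one motif, over a set of sequences
# concatenated with -1 padding (so windows never straddle two promoters).
.zoops_hits <- function(codes, starts, widths, pwm, score_fraction, floor) {
  lodds <- .pwm_lodds(pwm, floor)
  thr <- score_fraction * .pwm_max_score(pwm, floor)
  hit <- rep(FALSE, length(starts))
  for (strand in 1:2) {
    m <- if (strand == 1L) lodds
         else lodds[4:1, rev(seq_len(ncol(lodds))), drop = FALSE]
    sc <- scan_scores_cpp(codes, m)
    ok <- which(!is.na(sc) & sc >= thr)
    if (length(ok)) {
      idx <- findInterval(ok, starts)
      hit[unique(idx)] <- TRUE
    }
  }
  hit
}

.concat_codes <- function(seqs, pad) {
  codes <- lapply(as.character(seqs), .encode_seq)
  widths <- lengths(codes)
  gap <- rep(-1L, pad)
  joined <- unlist(lapply(codes, function(x) c(x, gap)), use.names = FALSE)
  starts <- cumsum(c(1L, widths[-length(widths)] + pad))
  list(codes = joined, starts = starts, widths = widths)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `fg_hits` hit-promoters when drawing
#' `fg_total` promoters from the pooled foreground + background collection
#' containing `fg_hits + bg_hits` hit-promoters (ZOOPS counting: a promoter
#' counts once however many motif occurrences it carries).
#'
#' @param fg_hits,fg_total Foreground promoters with a hit / total.
#' @param bg_hits,bg_total Background promoters with a hit / total.
#' @return p-value in (0, 1].
#' @export
enrichment_test <- function(fg_hits, fg_total, bg_hits, bg_total) {
  if (fg_total <= 0) stop_config("fg_total must be > 0")
  if (fg_hits < 0 || fg_hits > fg_total || bg_hits < 0 ||
      bg_hits > bg_total)
    stop_config("inconsistent hit counts")
  K <- fg_hits + bg_hits
  N <- fg_total + bg_total
  phyper(fg_hits - 1, K, N - K, fg_total, lower.tail = FALSE)
}

#' Motif enrichment of a foreground promoter set vs. a background
#'
#' Scans both sequence sets with every PWM ([scan_promoter()] scoring),
#' counts hit-promoters under ZOOPS, and tests each motif with the
#' upper-tail hypergeometric ([enrichment_test()]).  The intended
#' background is the promoters of genes whose expression did not change.
#'
#' @param fg,bg [Biostrings::DNAStringSet] (or character) promoter sets.
#' @param pwms Named list of [pwm()] objects.
#' @param score_fraction,floor See [scan_promoter()].
#' @return Data frame: `motif`, `fg_hits`, `fg_total`, `bg_hits`,
#'   `bg_total`, `p_value`, `neg_log10_p`.
#' @export
motif_enrichment <- function(fg, bg, pwms, score_fraction = 0.8,
                             floor = 1e-3) {
  if (!length(fg)) stop_config("foreground set is empty")
  pad <- max(vapply(pwms, function(p) ncol(p$mat), integer(1)))
  cf <- .concat_codes(fg, pad)
  cb <- .concat_codes(bg, pad)
  rows <- lapply(pwms, function(p) {
    fg_hits <- sum(.zoops_hits(cf$codes, cf$starts, cf$widths, p,
                               score_fraction, floor))
    bg_hits <- sum(.zoops_hits(cb$codes, cb$starts, cb$widths, p,
                               score_fraction, floor))
    pv <- enrichment_test(fg_hits, length(fg), bg_hits, length(bg))
    data.frame(motif = p$id, fg_hits = fg_hits, fg_total = length(fg),
               bg_hits = bg_hits, bg_total = length(bg), p_value = pv,
               neg_log10_p = -log10(pv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top-k motif lists and their pairwise overlaps
#'
#' For each enrichment result set, selects the `k` motifs with the smallest
#' p-values (ties broken by larger foreground hit count, then motif id) and
#' computes pairwise intersection sizes, plus the full motif-by-set
#' -log10(p) matrix for scatter comparisons.
#'
#' @param results_by_set Named list of [motif_enrichment()] outputs; every
#'   set must contain at least `k` motifs.
#' @param k Number of motifs per list (default 30).
#' @return List: `top` (named list of motif-id vectors), `overlap`
#'   (integer matrix of intersection sizes), `neg_log10_p` (data frame,
#'   motif by set).
#' @export
top_k_overlap <- function(results_by_set, k = 30L) {
  for (nm in names(results_by_set))
    if (nrow(results_by_set[[nm]]) < k)
      stop_config("set '%s' has fewer than k = %d motifs", nm, k)
  top <- lapply(results_by_set, function(r) {
    r <- r[order(r$p_value, -r$fg_hits, r$motif), , drop = FALSE]
    r$motif[seq_len(k)]
  })
  sets <- names(results_by_set)
  ov <- matrix(0L, length(sets), length(sets),
               dimnames = list(sets, sets))
  for (a in sets) for (b in sets)
    ov[a, b] <- length(intersect(top[[a]], top[[b]]))
  motifs <- results_by_set[[1]]$motif
  mat <- data.frame(motif = motifs, stringsAsFactors = FALSE)
  for (nm in sets) {
    r <- results_by_set[[nm]]
    mat[[nm]] <- r$neg_log10_p[match(motifs, r$motif)]
  }
  list(top = top, overlap = ov, neg_log10_p = mat)
}
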