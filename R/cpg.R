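#' Classify TSSs by CpG-island proximity
#'
#' A promoter is CpG-associated when its TSS lies inside a predicted CpG
#' island or within `max_dist` bp of the nearest island edge
#' (boundary-inclusive).  Distances use the half-open interval convention
#' of BED islands; a TSS on a chromosome with no islands gets infinite
#' distance and is not associated.  Because the gap is measured to the
#' nearest edge, merging overlapping islands never changes a call.
#'
#' @param tss Data frame with columns `gene_id`, `chrom`, `tss` (0-based
#'   position), e.g. the rank-1 transcripts of an annotation; a full
#'   annotation table is reduced to its rank-1 transcripts automatically.
#' @param islands Data frame of islands: `chrom`, `start`, `end` (0-based
#'   half-open, as in BED).
#' @param max_dist Association distance in bp (default 200).
#' @return Data frame: `gene_id`, `distance`, `associated`.
#' @export
classify_cpg <- function(tss, islands, max_dist = 200L) {
  if ("tx_rank" %in% names(tss))
    tss <- tss[tss$tx_rank == 1L, , drop = FALSE]
  need <- c("gene_id", "chrom", "tss")
  if (length(setdiff(need, names(tss))))
    stop_config("tss table needs columns gene_id, chrom, tss")
  if (any(islands$end <= islands$start))
    stop_config("island intervals must satisfy start < end")
  tss_gr <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(tss$tss + 1L, tss$tss + 1L))
  dist <- rep(Inf, nrow(tss))
  if (nrow(islands)) {
    isl_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      islands$chrom, IRanges::IRanges(islands$start + 1L, islands$end)))
    hits <- GenomicRanges::distanceToNearest(tss_gr, isl_gr)
    dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  }
  data.frame(gene_id = tss$gene_id, distance = dist,
             associated = dist <= max_dist, stringsAsFactors = FALSE)
}

#' CpG-association proportions per gene set
#'
#' Per-set fraction of CpG-associated promoters, plus pairwise 2x2
#' contingency comparisons (Fisher's exact test) between sets.
#'
#' @param classes Data frame with `gene_id` and `label` columns (e.g. from
#'   [build_gene_sets()]), or a named list of gene-id vectors.
#' @param calls Output of [classify_cpg()].
#' @return List: `proportions` (data frame `label`, `n`, `n_associated`,
#'   `fraction`) and `pairwise` (data frame `set_a`, `set_b`, `p_fisher`).
#'   Empty sets are skipped with a warning.
#' @export
set_proportions <- function(classes, calls) {
  if (is.list(classes) && !is.data.frame(classes)) {
    classes <- data.frame(
      gene_id = unlist(classes, use.names = FALSE),
      label = rep(names(classes), lengths(classes)),
      stringsAsFactors = FALSE)
  }
  m <- merge(classes, calls, by = "gene_id")
  if (!nrow(m)) stop_config("no genes shared between classes and calls")
  labs <- unique(classes$label)
  empty <- setdiff(labs, unique(m$label))
  if (length(empty))
    warning("empty set(s) skipped: ", paste(empty, collapse = ", "))
  labs <- setdiff(labs, empty)
  prop <- do.call(rbind, lapply(labs, function(l) {
    a <- m$associated[m$label == l]
    data.frame(label = l, n = length(a), n_associated = sum(a),
               fraction = mean(a), stringsAsFactors = FALSE)
  }))
  pair <- list()
  if (length(labs) > 1L) {
    cmb <- utils::combn(labs, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- prop[prop$label == cmb[1, j], ]
      b <- prop[prop$label == cmb[2, j], ]
      tab <- matrix(c(a$n_associated, a$n - a$n_associated,
                      b$n_associated, b$n - b$n_associated), nrow = 2)
      pair[[j]] <- data.frame(set_a = cmb[1, j], set_b = cmb[2, j],
                              p_fisher = fisher.test(tab)$p.value,
                              stringsAsFactors = FALSE)
    }
  }
  list(proportions = prop,
       pairwise = if (length(pair)) do.call(rbind, pair)
                  else data.frame(set_a = character(), set_b = character(),
                                  p_fisher = numeric(),
                                  stringsAsFactors = FALSE))
}
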