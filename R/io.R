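#' Write a coverage track as bedGraph
#'
#' Four-column bedGraph, 0-based half-open, sorted, with runs of equal
#' value merged and zero runs omitted.  The inverse of
#' [read_bedgraph()] up to the dropped zeros (which read back as zero).
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  tabs <- lapply(sort(names(track$counts)), function(ch) {
    r <- track$counts[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))          # 1-based run ends
    keep <- S4Vectors::runValue(r) != 0
    data.table::data.table(
      chrom = ch,
      start = (ends - S4Vectors::runLength(r))[keep], # 0-based half-open
      end = ends[keep],
      score = S4Vectors::runValue(r)[keep])
  })
  tab <- data.table::rbindlist(tabs)
  data.table::fwrite(tab, path, sep = "\t", col.names = FALSE,
                     scipen = 50)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path bedGraph path (4 columns, 0-based half-open).
#' @param total_reads Library size for RPM normalization.
#' @param chrom_lengths Named integer vector of chromosome lengths;
#'   positions not covered by any record are zero.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, total_reads, chrom_lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- GenomicRanges::coverage(gr, weight = "score",
                                 width = as.list(chrom_lengths))
  coverage_track(as.list(cov), total_reads)
}

# Annotation export: GTF (1-based closed) and BED12 (0-based half-open).
.annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(start = annotation$start + 1L, end = annotation$end),
    strand = annotation$strand,
    type = rep("exon", nrow(annotation)),
    source = rep("bstim", nrow(annotation)),
    gene_id = annotation$gene_id, transcript_id = annotation$tx_id)
}

write_annotation_gtf <- function(annotation, path) {
  if (nrow(annotation) == 0L) {              # rtracklayer rejects empties
    writeLines(character(0), path)
    return(invisible(path))
  }
  rtracklayer::export(.annotation_granges(annotation), path,
                      format = "gtf")
  invisible(path)
}

write_annotation_bed12 <- function(annotation, path) {
  if (nrow(annotation) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- .annotation_granges(annotation)
  grl <- S4Vectors::split(gr, gr$transcript_id)
  rtracklayer::export(grl, path, format = "bed")
  invisible(path)
}

#' Read a transcript annotation written by [write_dataset()]
#'
#' Reconstructs the internal transcript table (0-based TSSs, one row per
#' transcript) from a GTF of single-exon transcripts.
#'
#' @param path GTF path.
#' @return Transcript data frame as used by [select_anchors()].
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(
    gene_id = gr$gene_id, tx_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$tx_rank <- as.integer(sub(".*\\.t", "", df$tx_id))
  df[order(df$gene_id, df$tx_rank),
     c("gene_id", "tx_id", "tx_rank", "chrom", "start", "end", "strand",
       "tss")]
}

#' Write a generated dataset as standard files
#'
#' Emits BED12 + GTF annotation, one bedGraph per coverage track, TSV
#' expression and miRNA tables, FASTA genome and promoter sequences, a
#' JASPAR-style PWM library, a BED of CpG islands, a JSON ground truth and
#' a JSON manifest (files, chromosome lengths, library sizes).  Components
#' absent from the dataset are skipped.
#'
#' @param dataset A `bstim_dataset` from [generate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths (the manifest), invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  manifest <- list(chrom_lengths = stats::setNames(
    list(dataset$config$chrom_length), dataset$config$chrom))
  files <- list()

  files$annotation_gtf <- write_annotation_gtf(dataset$annotation,
                                               pth("annotation.gtf"))
  files$annotation_bed12 <- write_annotation_bed12(dataset$annotation,
                                                   pth("annotation.bed"))
  if (!is.null(dataset$tracks)) {
    manifest$library_sizes <- lapply(dataset$config$library_sizes, as.list)
    for (sig in names(dataset$tracks)) {
      for (cond in names(dataset$tracks[[sig]])) {
        f <- pth(sprintf("%s_%s.bedgraph", sig, cond))
        write_bedgraph(dataset$tracks[[sig]][[cond]], f)
        files[[sprintf("track_%s_%s", sig, cond)]] <- f
      }
    }
  }
  if (!is.null(dataset$expression))
    files$expression <- .write_tsv(dataset$expression,
                                   pth("expression.tsv"))
  if (!is.null(dataset$genome)) {
    Biostrings::writeXStringSet(dataset$genome, pth("genome.fa"))
    files$genome <- pth("genome.fa")
    if (nrow(dataset$annotation)) {
      prom <- extract_promoters(dataset$annotation, dataset$genome)
      Biostrings::writeXStringSet(prom, pth("promoters.fa"))
      files$promoters <- pth("promoters.fa")
    }
    files$pwms <- write_pwms(dataset$pwms, pth("motifs.jaspar"))
  }
  if (!is.null(dataset$mirna)) {
    files$mirna_normalized <- .write_tsv(dataset$mirna$normalized,
                                         pth("mirna_normalized.tsv"))
    files$mirna_counts <- .write_tsv(dataset$mirna$counts,
                                     pth("mirna_counts.tsv"))
    manifest$mirna_library_sizes <- as.list(dataset$mirna$library_sizes)
  }
  if (!is.null(dataset$cpg_islands)) {
    .write_tsv_noheader(dataset$cpg_islands, pth("cpg_islands.bed"))
    files$cpg_islands <- pth("cpg_islands.bed")
  }
  truth <- dataset$truth
  truth$gene_class <- as.list(truth$gene_class)
  if (!is.null(truth$mirna_category))
    truth$mirna_category <- as.list(truth$mirna_category)
  jsonlite::write_json(truth, pth("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files$ground_truth <- pth("ground_truth.json")

  manifest$files <- lapply(files, basename)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files$manifest <- pth("manifest.json")
  invisible(files)
}

.write_tsv_noheader <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a TSV expression or miRNA table
#'
#' @param path TSV path with a header row.
#' @return Data frame.
#' @export
read_table_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a BED file of CpG islands
#'
#' @param path BED path (first three columns used).
#' @return Data frame `chrom`, `start`, `end` (0-based half-open).
#' @export
read_cpg_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}
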