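`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Multiplier lookup tolerant of classes absent from an effects table.
.effect_mult <- function(effects, class, field, condition) {
  e <- effects[[class]]
  if (is.null(e)) return(1)
  if (!is.null(field)) e <- e[[field]]
  if (is.null(e)) return(1)
  v <- e[[condition]]
  if (is.null(v) || is.na(v)) 1 else v
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
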