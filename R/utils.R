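# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_np <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_np(sprintf("'%s' must be a proportion in [0, 1]", name))
  invisible(x)
}

assert_gene_set <- function(x, name = "gene set") {
  if (!is.character(x)) stop_np(name, " must be a character vector of gene ids")
  invisible(unique(x))
}

# Derive a reproducible substream seed from a master seed and a stream label.
# Keeps the derived seed strictly below .Machine$integer.max.
substream_seed <- function(seed, stream) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_np("'seed' must be a single integer")
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L)
}

# Deterministic TSV writer used for all emitted tables.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
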