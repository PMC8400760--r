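# Internal helpers shared across modules.

#' Derive a reproducible substream seed
#'
#' Mixes a root seed with a sequence of non-negative integer indices into a
#' single seed below 2^31, so that any unit of work (a dataset, a permutation,
#' a (repeat, fold, model) cell) owns an independently reproducible RNG stream.
#'
#' @param seed root integer seed.
#' @param ... integer indices identifying the substream.
#' @return a single integer in [1, 2^31 - 2].
#' @keywords internal
substream_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in idx) {
    # Lehmer-style mixing; stays within exact double integer range.
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s) + 1L
}

#' Soft-thresholding operator
#'
#' @param a numeric vector.
#' @param delta non-negative threshold.
#' @return sign(a) * max(|a| - delta, 0), elementwise.
#' @keywords internal
soft_threshold <- function(a, delta) {
  sign(a) * pmax(abs(a) - delta, 0)
}

# scale() wrapper that errors informatively on constant columns.
standardize_columns <- function(x, what = "matrix") {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(x)[sds == 0 | !is.finite(sds)]
    if (is.null(bad)) bad <- which(sds == 0 | !is.finite(sds))
    stop(sprintf("constant column(s) in %s: %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  scale(x, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

# Deterministic TSV writer used by every CLI subcommand: fixed quoting,
# fixed NA representation, 15 significant digits, no row names unless asked.
write_tsv_file <- function(x, path, row_label = NULL) {
  df <- as.data.frame(x, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 15, format = "g"))
  if (!is.null(row_label)) {
    df <- cbind(stats::setNames(data.frame(rownames(as.data.frame(x)),
                                           stringsAsFactors = FALSE), row_label), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
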