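#' Symmetric Procrustes concordance test
#'
#' Compares the leading axes of two ordinations of the same samples. Both
#' configurations are column-centered and scaled to unit total sum of squares;
#' the optimal rotation comes from the SVD of the cross-product, giving the
#' minimized sum of squared differences `m2 = 1 - (sum of singular values)^2`
#' and the concordance statistic `t = sqrt(1 - m2)`. Significance is assessed
#' by permuting the rows of one configuration: `p = (1 + #{t_perm >= t_obs}) /
#' (n_perm + 1)` (the add-one Monte-Carlo estimator, which never returns 0).
#'
#' Because Procrustes removes translation, rotation/reflection and uniform
#' scaling, two configurations that differ only by such a similarity transform
#' give `m2 = 0`, `t = 1`.
#'
#' @param ord_a,ord_b `ordination` objects (or bare coordinate matrices) over
#'   the same samples in the same order; no silent realignment is performed.
#' @param n_axes number of leading axes compared (default 2).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param keep_permutations if `TRUE`, the permuted t statistics are returned.
#' @return a `procrustes_result`: list with `m2`, `t_stat`, `p_value`,
#'   `n_perm`, and optionally `permuted_t`.
#' @export
procrustes_test <- function(ord_a, ord_b, n_axes = 2, n_perm = 999, seed = 1L,
                            keep_permutations = FALSE) {
  A <- procrustes_config(ord_a, n_axes)
  B <- procrustes_config(ord_b, n_axes)
  ids_a <- rownames(A); ids_b <- rownames(B)
  if (!is.null(ids_a) && !is.null(ids_b) && !identical(ids_a, ids_b))
    stop("sample order differs between the two ordinations")
  if (nrow(A) != nrow(B)) stop("ordinations have different sample counts")
  t_obs <- procrustes_t(A, B)
  set.seed(substream_seed(seed, 101L))
  t_perm <- vapply(seq_len(n_perm), function(i) {
    procrustes_t(A, B[sample.int(nrow(B)), , drop = FALSE])
  }, numeric(1))
  p <- (1 + sum(t_perm >= t_obs)) / (n_perm + 1)
  structure(list(m2 = 1 - t_obs^2, t_stat = t_obs, p_value = p,
                 n_perm = as.integer(n_perm),
                 permuted_t = if (keep_permutations) t_perm else NULL),
            class = "procrustes_result")
}

# Center and unit-sum-of-squares scale the first n_axes columns.
procrustes_config <- function(ord, n_axes) {
  X <- if (inherits(ord, "ordination")) ord$coordinates else as.matrix(ord)
  if (ncol(X) < n_axes)
    stop(sprintf("ordination has %d axes, %d requested", ncol(X), n_axes))
  X <- X[, seq_len(n_axes), drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  ss <- sum(X^2)
  if (ss == 0) stop("degenerate configuration: zero total sum of squares")
  X / sqrt(ss)
}

# Procrustes statistic t = sum of singular values of t(A) %*% B for two
# centered, unit-scaled configurations; m2 = 1 - t^2.
procrustes_t <- function(A, B) {
  sum(svd(crossprod(A, B))$d)
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes: m2 = %.4f, t = %.4f, p = %.4g (%d permutations)\n",
              x$m2, x$t_stat, x$p_value, x$n_perm))
  invisible(x)
}
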