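#' Pairwise Spearman screening with Benjamini-Hochberg control
#'
#' Computes Spearman's rank correlation (average ranks for ties) between every
#' (taxon, metabolite) column pair, a two-sided p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom, and Benjamini-Hochberg adjusted q-values across all pairs jointly.
#' Pairs involving a constant column have undefined correlation; they are
#' recorded as `NA` and excluded from the BH family.
#'
#' @param taxa_matrix numeric matrix, samples x taxa (typically the CLR genus
#'   matrix).
#' @param metab_matrix numeric matrix, samples x metabolites (typically on the
#'   variance-stabilized scale; Spearman is invariant to the monotone
#'   per-metabolite transforms).
#' @param fdr significance cutoff applied to q-values (default 0.05).
#' @return an `association_matrix`: list of matrices `rho`, `p_value`,
#'   `q_value`, logical `significant`, plus `fdr`.
#' @export
spearman_association_matrix <- function(taxa_matrix, metab_matrix, fdr = 0.05) {
  X <- as.matrix(taxa_matrix); Z <- as.matrix(metab_matrix)
  if (nrow(X) != nrow(Z)) stop("matrices must have the same sample count")
  n <- nrow(X)
  if (n < 3) stop("at least 3 samples are required")
  const_x <- apply(X, 2, function(v) length(unique(v)) == 1)
  const_z <- apply(Z, 2, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(stats::cor(X, Z, method = "spearman"))
  rho[const_x, ] <- NA; rho[, const_z] <- NA
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  q <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  structure(list(rho = rho, p_value = p, q_value = q,
                 significant = !is.na(q) & q < fdr, fdr = fdr),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix: %d x %d pairs, %d significant at q < %g\n",
              nrow(x$rho), ncol(x$rho), sum(x$significant), x$fdr))
  invisible(x)
}
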