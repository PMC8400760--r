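#' Generalized UniFrac distance
#'
#' Branch-length-weighted community dissimilarity between all sample pairs of
#' a relative-abundance table, with abundance-weighting exponent `alpha`. For
#' a branch `b` of length `l_b` whose descendant leaves carry total
#' proportions `p_b` and `q_b` in the two samples,
#' \deqn{d = \frac{\sum_b l_b (p_b + q_b)^\alpha |p_b - q_b| / (p_b + q_b)}
#'              {\sum_b l_b (p_b + q_b)^\alpha},}
#' with branches where `p_b + q_b = 0` skipped. `alpha = 1` is weighted
#' (normalized) UniFrac; `alpha = 0.5` (the default used throughout this
#' package) moderates the influence of highly abundant lineages. Distances lie
#' in `[0, 1]` and are computed on the unfiltered ASV-level table normalized
#' to relative abundances, because the tree's leaves are ASVs.
#'
#' @param table [feature_table] of relative abundances whose feature ids all
#'   appear among the tree's leaf labels (rows should sum to 1).
#' @param tree a rooted `phylo` covering the table's features.
#' @param alpha abundance-weighting exponent in `[0, 1]`.
#' @return a `dist_matrix`: symmetric matrix with zero diagonal and
#'   attributes `metric = "gunifrac"` and `gunifrac_alpha`.
#' @export
gunifrac <- function(table, tree, alpha = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  missing_leaves <- setdiff(table$feature_ids, tree$tip.label)
  if (length(missing_leaves))
    stop("feature(s) absent from the tree: ",
         paste(utils::head(missing_leaves, 10), collapse = ", "))
  P <- branch_proportions(table, tree)       # samples x edges (postorder)
  L <- attr(P, "edge_lengths")
  n <- nrow(P)
  d <- matrix(0, n, n, dimnames = list(table$sample_ids, table$sample_ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- P[i, ]; q <- P[j, ]
      s <- p + q
      act <- s > 0
      if (!any(act)) next
      w <- L[act] * s[act]^alpha
      d[i, j] <- d[j, i] <- sum(w * abs(p[act] - q[act]) / s[act]) / sum(w)
    }
  }
  dist_matrix(d, metric = "gunifrac", gunifrac_alpha = alpha)
}

# Per-edge descendant-leaf proportion totals for every sample, by postorder
# accumulation: the value of an edge is the value of its child node.
branch_proportions <- function(table, tree) {
  tr <- stats::reorder(tree, "postorder")
  n_tip <- ape::Ntip(tr)
  n_node <- n_tip + tr$Nnode
  vals <- matrix(0, nrow = n_node, ncol = nrow(table$values))
  idx <- match(tr$tip.label, table$feature_ids)
  present <- !is.na(idx)
  vals[which(present), ] <- t(table$values[, idx[present], drop = FALSE])
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    vals[parent, ] <- vals[parent, ] + vals[child, ]
  }
  P <- t(vals[tr$edge[, 2], , drop = FALSE])    # samples x edges
  rownames(P) <- table$sample_ids
  # hand the caller edges in the same order as tr$edge.length
  attr(P, "edge_lengths") <- tr$edge.length
  P
}

#' Construct a distance-matrix object
#'
#' @param values symmetric non-negative matrix with zero diagonal.
#' @param metric label of the metric.
#' @param gunifrac_alpha optional exponent recorded for gUniFrac matrices.
#' @return the matrix, classed `dist_matrix`.
#' @export
dist_matrix <- function(values, metric = "euclidean", gunifrac_alpha = NULL) {
  values <- as.matrix(values)
  if (max(abs(values - t(values))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(values) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(values < 0)) stop("distances must be non-negative")
  structure(values, metric = metric, gunifrac_alpha = gunifrac_alpha,
            class = c("dist_matrix", "matrix", "array"))
}

#' Euclidean sample distances of a transformed data matrix
#'
#' @param x numeric matrix, samples in rows (e.g. a CLR matrix or transformed
#'   metabolite matrix).
#' @return a `dist_matrix`.
#' @export
euclidean_distance <- function(x) {
  dist_matrix(as.matrix(stats::dist(x)), metric = "euclidean")
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the doubly centered squared-distance matrix
#' `B = -1/2 J (D o D) J` with `J` the centering projector. Coordinates are
#' eigenvectors scaled by the square root of their (positive) eigenvalues;
#' negative eigenvalues — possible for non-Euclidean dissimilarities such as
#' generalized UniFrac — are reported unchanged but carry no coordinates. No
#' Cailliez/Lingoes correction is applied.
#'
#' @param D a `dist_matrix` (or symmetric matrix).
#' @param k number of axes requested; truncated with a warning if it exceeds
#'   the number of positive eigenvalues.
#' @return an `ordination`: list with `coordinates` (samples x k'),
#'   `eigenvalues` (all, descending), `sample_ids`, `k`.
#' @export
pcoa <- function(D, k = 2) {
  D <- as.matrix(D)
  stopifnot(k >= 1)
  n <- nrow(D)
  A <- -0.5 * D^2
  # double centering
  B <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  if (length(pos) < k) {
    if (length(pos) < k && max(abs(eig$values)) > 0)
      warning(sprintf("only %d positive eigenvalue(s); truncating k from %d",
                      length(pos), k))
    k_eff <- length(pos)
  } else k_eff <- k
  axes <- pos[seq_len(k_eff)]
  coords <- eig$vectors[, axes, drop = FALSE] %*%
    diag(sqrt(eig$values[axes]), nrow = k_eff)
  rownames(coords) <- rownames(D)
  colnames(coords) <- if (k_eff > 0) paste0("Axis", seq_len(k_eff)) else NULL
  structure(list(coordinates = coords, eigenvalues = eig$values,
                 sample_ids = rownames(D), k = k_eff),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d samples, %d axes; leading eigenvalues: %s\n",
              length(x$sample_ids), x$k,
              paste(signif(utils::head(x$eigenvalues, 3), 4), collapse = ", ")))
  invisible(x)
}
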