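#' Generate a sparse compositional community table
#'
#' Log-normal abundances (meanlog 0, sdlog 1) masked to a target zero
#' fraction and closed to row proportions — a generic stand-in for a
#' processed relative-abundance table when no real community matrix is
#' supplied. Rows that come out all-zero are regenerated (bounded retries).
#'
#' @param n_samples,n_taxa table dimensions (>= 2 each).
#' @param sparsity probability a cell is zeroed, in `[0, 1)`.
#' @param seed integer seed.
#' @return a [feature_table] of proportions, rows summing to 1.
#' @export
generate_community <- function(n_samples, n_taxa, sparsity = 0.3, seed = 1L) {
  stopifnot(n_samples >= 2, n_taxa >= 2, sparsity >= 0, sparsity < 1)
  set.seed(substream_seed(seed, 613L))
  vals <- matrix(stats::rlnorm(n_samples * n_taxa), n_samples, n_taxa)
  if (sparsity > 0) {
    mask <- matrix(stats::runif(n_samples * n_taxa) < sparsity,
                   n_samples, n_taxa)
    vals[mask] <- 0
  }
  for (i in which(rowSums(vals) == 0)) {
    for (try in 1:100) {
      row <- stats::rlnorm(n_taxa)
      if (sparsity > 0) row[stats::runif(n_taxa) < sparsity] <- 0
      if (sum(row) > 0) break
    }
    if (sum(row) == 0) stop("could not generate a non-empty community row")
    vals[i, ] <- row
  }
  vals <- vals / rowSums(vals)
  dimnames(vals) <- list(paste0("S", seq_len(n_samples)),
                         paste0("taxon", seq_len(n_taxa)))
  feature_table(vals)
}

#' Bootstrap the rows of a community matrix
#'
#' Samples rows with replacement, mirroring the use of bootstrapped resamples
#' of a processed community matrix as simulation predictors.
#'
#' @param x [feature_table] or matrix.
#' @param n number of rows to draw (default: as many as the input has).
#' @param seed integer seed.
#' @return object of the same class with `n` rows, relabeled `S1..Sn`.
#' @export
bootstrap_community <- function(x, n = NULL, seed = 1L) {
  m <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  n <- n %||% nrow(m)
  set.seed(substream_seed(seed, 719L))
  out <- m[sample.int(nrow(m), n, replace = TRUE), , drop = FALSE]
  rownames(out) <- paste0("S", seq_len(n))
  if (inherits(x, "feature_table")) feature_table(out, allow_negative = TRUE)
  else out
}

#' Simulate a metabolite linearly coupled to taxa
#'
#' The positive simulation arm: each coefficient is zero with probability
#' `p_zero`, otherwise standard normal; the outcome is
#' `Y = beta0 + X beta + eps` with `eps ~ N(0, sigma_eps^2)` and
#' `sigma_eps = sd(beta0 + X beta) / snr` (sample standard deviation, n - 1
#' denominator), so the realized signal-to-noise ratio equals `snr` exactly
#' by construction. When the signal is constant (all coefficients zero, or
#' degenerate X), `sigma_eps` is undefined and falls back to 1 with a
#' warning and a `degenerate` flag.
#'
#' @param X numeric predictor matrix (CLR scale), samples in rows.
#' @param p_zero probability each coefficient is zero.
#' @param snr target signal-to-noise ratio (> 0).
#' @param beta0 intercept, default `6 / sqrt(10)`.
#' @param seed integer seed.
#' @return a `simulated_dataset`: list with `X`, `beta`, `beta0`,
#'   `epsilon_sd`, `epsilon`, `Y`, `snr`, `p_zero`, `degenerate`.
#' @export
simulate_linear_metabolite <- function(X, p_zero, snr, beta0 = 6 / sqrt(10),
                                       seed = 1L) {
  X <- as.matrix(X)
  stopifnot(p_zero >= 0, p_zero <= 1, snr > 0)
  set.seed(substream_seed(seed, 823L))
  p <- ncol(X)
  beta <- stats::rnorm(p)
  beta[stats::runif(p) < p_zero] <- 0
  signal <- beta0 + as.numeric(X %*% beta)
  sd_signal <- stats::sd(signal)
  degenerate <- sd_signal == 0
  if (degenerate) {
    warning("constant signal (all coefficients zero); sigma_eps set to 1")
    epsilon_sd <- 1
  } else {
    epsilon_sd <- sd_signal / snr
  }
  epsilon <- stats::rnorm(nrow(X), 0, epsilon_sd)
  structure(list(X = X, beta = beta, beta0 = beta0, epsilon_sd = epsilon_sd,
                 epsilon = epsilon, Y = signal + epsilon, snr = snr,
                 p_zero = p_zero, degenerate = degenerate),
            class = "simulated_dataset")
}

#' Richness-preserving shuffle of a community table
#'
#' Independently permutes each sample's values across taxa, preserving the
#' per-sample value multiset — hence row sums and richness (count of
#' non-zero taxa) — while destroying taxon identity. This is the richness
#' null model used by the sparse-CCA permutation test and the negative
#' simulation arm.
#'
#' @param table [feature_table] or matrix.
#' @param seed integer seed.
#' @return shuffled object of the same class.
#' @export
richness_shuffle <- function(table, seed = 1L) {
  m <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  set.seed(substream_seed(seed, 907L))
  out <- shuffle_within_rows(m)
  dimnames(out) <- dimnames(m)
  if (inherits(table, "feature_table")) feature_table(out, allow_negative = TRUE)
  else out
}

# Community proportions -> CLR predictors: a count-like pseudocount (depth
# 1e4, +1) restores positivity before closure, mirroring the preprocessing
# pseudocount treatment of zeros.
community_to_clr <- function(props, depth = 1e4) {
  counts <- props * depth + 1
  clr_transform(counts / rowSums(counts))
}

#' Run the simulation study
#'
#' Positive arm: for every `(p_zero, snr)` cell and dataset index, bootstrap
#' the base community rows, map to CLR, simulate the outcome with
#' [simulate_linear_metabolite()], split 80/20 into train/test, tune each
#' learner by `tune_folds`-fold cross-validation on the training 80%, refit
#' and score the held-out 20% (predictive R-squared and Spearman
#' correlation). Null arm: a single reference outcome is simulated, then for
#' each permutation the community is richness-shuffled — decoupling X from
#' the fixed Y — and the same split/tune/evaluate pipeline is applied.
#'
#' @param p_zero_grid,snr_grid simulation grid values.
#' @param n_datasets datasets per grid cell (default 100).
#' @param models learner names from the prediction benchmark.
#' @param n_samples,n_taxa community dimensions.
#' @param n_null permutations of the null arm (0 disables it; 500 matches
#'   the default design, 1000 is also in use).
#' @param beta0 simulation intercept.
#' @param train_frac training fraction of the split.
#' @param tune_folds folds of the tuning cross-validation (default 10).
#' @param seed root seed; every (cell, dataset) and permutation owns a
#'   substream.
#' @return data.frame with columns `arm` (`"positive"`/`"null"`), `model`,
#'   `p_zero`, `snr`, `index`, `r2`, `scc`.
#' @export
run_simulation_study <- function(p_zero_grid = c(0.05, 0.1, 0.5, 0.95),
                                 snr_grid = c(0.5, 0.7, 3, 5),
                                 n_datasets = 100L,
                                 models = c("rf", "svm_rbf", "enet", "spls"),
                                 n_samples = 100L, n_taxa = 50L,
                                 n_null = 0L, beta0 = 6 / sqrt(10),
                                 train_frac = 0.8, tune_folds = 10L,
                                 seed = 1L) {
  stopifnot(length(p_zero_grid) >= 1, length(snr_grid) >= 1, n_datasets >= 1)
  base <- generate_community(n_samples, n_taxa, sparsity = 0.3, seed = seed)
  grid <- expand.grid(p_zero = p_zero_grid, snr = snr_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    for (d in seq_len(n_datasets)) {
      # key the dataset stream on (p_zero, dataset) only: along the SNR axis
      # the community bootstrap, coefficient draw and standardized noise are
      # shared (common random numbers) and only the noise scale changes
      pi <- match(grid$p_zero[g], p_zero_grid)
      cell_seed <- substream_seed(seed, pi, d)
      boot <- bootstrap_community(base, n_samples, seed = cell_seed)
      Xc <- community_to_clr(boot$values)
      sim <- suppressWarnings(
        simulate_linear_metabolite(Xc, grid$p_zero[g], grid$snr[g],
                                   beta0 = beta0, seed = cell_seed))
      res <- evaluate_split(Xc, sim$Y, models, train_frac, tune_folds,
                            seed = cell_seed)
      res$arm <- "positive"; res$p_zero <- grid$p_zero[g]
      res$snr <- grid$snr[g]; res$index <- d
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (n_null > 0) {
    ref_seed <- substream_seed(seed, 9999L)
    boot <- bootstrap_community(base, n_samples, seed = ref_seed)
    sim <- suppressWarnings(
      simulate_linear_metabolite(community_to_clr(boot$values),
                                 p_zero_grid[1], snr_grid[1],
                                 beta0 = beta0, seed = ref_seed))
    for (i in seq_len(n_null)) {
      perm_seed <- substream_seed(seed, 9999L, i)
      Xp <- community_to_clr(richness_shuffle(boot, seed = perm_seed)$values)
      res <- evaluate_split(Xp, sim$Y, models, train_frac, tune_folds,
                            seed = perm_seed)
      res$arm <- "null"; res$p_zero <- p_zero_grid[1]
      res$snr <- snr_grid[1]; res$index <- i
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out[, c("arm", "model", "p_zero", "snr", "index", "r2", "scc")]
}

# One 80/20 split: tune on the training portion, refit, score the test set.
evaluate_split <- function(X, y, models, train_frac, tune_folds, seed) {
  n <- nrow(X)
  set.seed(substream_seed(seed, 31L))
  n_train <- max(tune_folds, round(train_frac * n))
  tr_idx <- sample.int(n, n_train)
  te_idx <- setdiff(seq_len(n), tr_idx)
  res <- lapply(seq_along(models), function(mi) {
    m <- models[mi]
    mseed <- substream_seed(seed, 37L, mi)
    hp <- inner_cv_select(m, X[tr_idx, , drop = FALSE], y[tr_idx],
                          n_folds = tune_folds, seed = mseed)
    pred <- fit_predict(m, hp, X[tr_idx, , drop = FALSE], y[tr_idx],
                        X[te_idx, , drop = FALSE], seed = mseed)
    met <- fold_metrics(y[te_idx], pred, inverse = "identity")
    data.frame(model = m, r2 = met$r2, scc = met$scc)
  })
  do.call(rbind, res)
}
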