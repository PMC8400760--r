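#' Hyperparameter grids for the four benchmark learners
#'
#' Grids follow common microbiome machine-learning benchmark practice:
#' * `rf` — a single configuration: 500 trees, `floor(sqrt(p))` candidate
#'   features per split.
#' * `svm_rbf` — cost `C` in `2^{-5}, 2^{-3}, ..., 2^{15}` (11 values) crossed
#'   with kernel width `gamma` in `2^{-15}, 2^{-13}, ..., 2^{3}` (10 values).
#' * `enet` — mixing values spaced by 0.1 between pure LASSO and pure ridge,
#'   each with a 100-value geometric lambda path from the training-fold
#'   `lambda_max` down four orders of magnitude. The `mixing` column is the
#'   weight on the L2 term (`mixing = 0` is the LASSO, `mixing = 1` is
#'   ridge); some software uses the reverse convention for its `alpha`, but
#'   since the full grid is swept the two conventions fit identical model
#'   sets.
#' * `spls` — components `K` in `1..10` crossed with threshold `eta` in
#'   `0.1..0.9`, concavity `kappa` fixed at 0.5.
#'
#' @param model_kind one of `"rf"`, `"svm_rbf"`, `"enet"`, `"spls"`.
#' @return a `hyper_grid`: list with `model_kind`, `grid` (data.frame of
#'   tunable combinations), and `fixed` (non-tuned settings).
#' @export
make_hyperparameter_grid <- function(model_kind = c("rf", "svm_rbf", "enet", "spls")) {
  model_kind <- match.arg(model_kind)
  out <- switch(model_kind,
    rf = list(grid = data.frame(n_trees = 500),
              fixed = list(mtry_rule = "sqrt_p")),
    svm_rbf = list(grid = expand.grid(cost = 2^seq(-5, 15, by = 2),
                                      gamma = 2^seq(-15, 3, by = 2)),
                   fixed = list()),
    enet = list(grid = data.frame(mixing = seq(0, 1, by = 0.1)),
                fixed = list(n_lambda = 100L, lambda_min_ratio = 1e-4)),
    spls = list(grid = expand.grid(K = 1:10, eta = seq(0.1, 0.9, by = 0.1)),
                fixed = list(kappa = 0.5)))
  structure(c(list(model_kind = model_kind), out), class = "hyper_grid")
}

#' Number of hyperparameter combinations in a grid
#' @param grid a `hyper_grid`.
#' @return integer count (lambda path counted for `enet`).
#' @export
n_combinations <- function(grid) {
  n <- nrow(grid$grid)
  if (grid$model_kind == "enet") n <- n * grid$fixed$n_lambda
  as.integer(n)
}

#' Fit one learner and predict held-out samples
#'
#' Model contracts: `rf` bags 500 regression trees with `floor(sqrt(p))`
#' candidate features per split; `svm_rbf` is epsilon-insensitive support
#' vector regression with Gaussian kernel `exp(-gamma ||x - x'||^2)`; `enet`
#' minimizes squared error plus `lambda [(1 - r) ||b||_1 + r ||b||_2^2 / 2]`
#' where `r` is the `mixing` weight on the L2 term; `spls` is sparse partial
#' least squares with soft-thresholded direction vectors (threshold `eta`,
#' `K` components). All fits are deterministic given `seed`.
#'
#' @param model_kind learner name.
#' @param hyperparams named list of hyperparameters for that learner
#'   (`rf`: `n_trees`; `svm_rbf`: `cost`, `gamma`; `enet`: `mixing`,
#'   `lambda`; `spls`: `K`, `eta`).
#' @param X_train,y_train training predictors/outcome (outcome on the
#'   transformed scale).
#' @param X_test matrix with the same columns as `X_train`.
#' @param seed integer seed (consumed by the tree bagging).
#' @return numeric vector of predictions for `X_test` rows.
#' @export
fit_predict <- function(model_kind, hyperparams, X_train, y_train, X_test,
                        seed = 1L) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (!identical(colnames(X_train), colnames(X_test)) &&
      ncol(X_train) != ncol(X_test))
    stop("train and test predictor spaces differ")
  if (stats::sd(y_train) == 0) {
    return(rep(y_train[1], nrow(X_test)))
  }
  switch(model_kind,
    rf = {
      set.seed(substream_seed(seed, 11L))
      fit <- randomForest::randomForest(
        x = X_train, y = y_train,
        ntree = hyperparams$n_trees %||% 500,
        mtry = max(1L, floor(sqrt(ncol(X_train)))))
      as.numeric(stats::predict(fit, X_test))
    },
    svm_rbf = {
      fit <- e1071::svm(x = X_train, y = y_train, type = "eps-regression",
                        kernel = "radial", cost = hyperparams$cost,
                        gamma = hyperparams$gamma)
      as.numeric(stats::predict(fit, X_test))
    },
    enet = {
      # the requested lambda generally comes from a path computed on other
      # data; refit with it spliced into this fold's path so the prediction
      # is exact rather than interpolated
      a <- 1 - hyperparams$mixing
      path_fit <- glmnet::glmnet(X_train, y_train, alpha = a,
                                 nlambda = 100, lambda.min.ratio = 1e-4)
      lams <- sort(unique(c(path_fit$lambda, hyperparams$lambda)),
                   decreasing = TRUE)
      fit <- glmnet::glmnet(X_train, y_train, alpha = a, lambda = lams)
      as.numeric(stats::predict(fit, X_test, s = hyperparams$lambda))
    },
    spls = {
      fit <- spls_fit(X_train, y_train, K = hyperparams$K,
                      eta = hyperparams$eta,
                      kappa = hyperparams$kappa %||% 0.5)
      spls_predict(fit, X_test)
    },
    stop("unknown model_kind: ", model_kind))
}

# ---- sparse partial least squares (univariate outcome) ---------------------
# Direction vectors are soft-thresholded cross-covariances (threshold a
# fraction eta of the largest absolute entry); the active set accumulates
# across components and a plain PLS fit on the active predictors gives the
# coefficients. kappa is the concavity parameter of the general formulation;
# for a univariate outcome the surrogate-direction solution reduces to the
# thresholding form, so kappa is carried but inert.
spls_fit <- function(X, y, K, eta, kappa = 0.5) {
  X <- as.matrix(X)
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd)
  sx[sx == 0] <- 1
  Xs <- scale(X, center = mx, scale = sx)
  my <- mean(y); yc <- y - my
  p <- ncol(Xs)
  active <- integer(0)
  beta_s <- numeric(p)
  y_res <- yc
  for (k in seq_len(K)) {
    z <- as.numeric(crossprod(Xs, y_res))
    thr <- eta * max(abs(z))
    w <- soft_threshold(z, thr)
    active <- sort(union(active, which(w != 0)))
    if (length(active) == 0) break
    beta_a <- pls_coefficients(Xs[, active, drop = FALSE], yc,
                               ncomp = min(k, length(active)))
    beta_s <- numeric(p)
    beta_s[active] <- beta_a
    y_res <- yc - Xs %*% beta_s
  }
  list(beta_s = beta_s, mx = mx, sx = sx, my = my, kappa = kappa)
}

spls_predict <- function(fit, X_new) {
  Xs <- scale(as.matrix(X_new), center = fit$mx, scale = fit$sx)
  as.numeric(Xs %*% fit$beta_s + fit$my)
}

# One SPLS sweep to K_max components, recording the coefficient vector after
# each component, so a whole K-path costs one fit (used by the inner CV).
spls_fit_path <- function(X, y, K_max, eta, kappa = 0.5) {
  X <- as.matrix(X)
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd)
  sx[sx == 0] <- 1
  Xs <- scale(X, center = mx, scale = sx)
  my <- mean(y); yc <- y - my
  p <- ncol(Xs)
  active <- integer(0)
  beta_s <- numeric(p)
  y_res <- yc
  betas <- vector("list", K_max)
  for (k in seq_len(K_max)) {
    z <- as.numeric(crossprod(Xs, y_res))
    thr <- eta * max(abs(z))
    w <- soft_threshold(z, thr)
    active <- sort(union(active, which(w != 0)))
    if (length(active) > 0) {
      beta_a <- pls_coefficients(Xs[, active, drop = FALSE], yc,
                                 ncomp = min(k, length(active)))
      beta_s <- numeric(p)
      beta_s[active] <- beta_a
      y_res <- yc - Xs %*% beta_s
    }
    betas[[k]] <- beta_s
  }
  list(betas = betas, mx = mx, sx = sx, my = my, kappa = kappa)
}

# NIPALS partial least squares regression coefficients, univariate outcome.
pls_coefficients <- function(X, y, ncomp) {
  E <- X; f <- y
  p <- ncol(X)
  W <- P <- matrix(0, p, 0)
  q <- numeric(0)
  for (k in seq_len(ncomp)) {
    w <- as.numeric(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_sc <- as.numeric(E %*% w)
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p_load <- as.numeric(crossprod(E, t_sc)) / tt
    q_load <- sum(f * t_sc) / tt
    E <- E - tcrossprod(t_sc, p_load)
    f <- f - t_sc * q_load
    W <- cbind(W, w); P <- cbind(P, p_load); q <- c(q, q_load)
  }
  if (ncol(W) == 0) return(numeric(p))
  as.numeric(W %*% solve(crossprod(P, W), q))
}

#' Held-out fold metrics on the back-transformed scale
#'
#' Both vectors are mapped back to the original concentration scale via the
#' inverse transform, then scored with predictive R-squared
#' `1 - PRESS / TSS` — where `TSS` is taken about the held-out fold's own
#' mean, so the naive fold-mean predictor scores exactly 0 and worse-than-mean
#' predictions go negative — and the Spearman correlation of truth vs
#' prediction.
#'
#' @param y_true,y_pred vectors on the transformed scale (length >= 3).
#' @param inverse transform kind to invert, as in
#'   [inverse_transform_metabolites()].
#' @return list with `r2` (NA when the back-transformed truth is constant)
#'   and `scc`.
#' @export
fold_metrics <- function(y_true, y_pred, inverse = "identity") {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 3) stop("at least 3 held-out values are required")
  yt <- inverse_transform_metabolites(y_true, inverse)
  yp <- inverse_transform_metabolites(y_pred, inverse)
  tss <- sum((yt - mean(yt))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - sum((yt - yp)^2) / tss
  scc <- if (stats::sd(yt) == 0 || stats::sd(yp) == 0) NA_real_ else
    suppressWarnings(stats::cor(yt, yp, method = "spearman"))
  list(r2 = r2, scc = scc)
}

#' Cross-validation plan
#'
#' @param n_repeats repeats of the outer loop (default 100).
#' @param n_outer_folds outer folds per repeat (default 5).
#' @param n_inner_folds inner folds for hyperparameter selection (default 5).
#' @param seed root seed; every (repeat, fold, model) unit derives its own
#'   substream, so any cell is independently reproducible.
#' @return a `cv_plan` list.
#' @export
cv_plan <- function(n_repeats = 100L, n_outer_folds = 5L, n_inner_folds = 5L,
                    seed = 1L) {
  stopifnot(n_repeats >= 1, n_outer_folds >= 2, n_inner_folds >= 2)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_outer_folds = as.integer(n_outer_folds),
                 n_inner_folds = as.integer(n_inner_folds),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

# Fold labels partitioning n samples into k folds of near-equal size.
make_folds <- function(n, k) {
  sample(rep(seq_len(k), length.out = n))
}

# R-squared on the transformed scale used as the inner selection criterion.
inner_r2 <- function(y_true, y_pred) {
  tss <- sum((y_true - mean(y_true))^2)
  if (tss == 0) return(NA_real_)
  1 - sum((y_true - y_pred)^2) / tss
}

#' Select hyperparameters by inner cross-validation
#'
#' Evaluates every grid point by `n_folds`-fold cross-validation on the
#' training portion, scoring mean R-squared on the transformed scale, and
#' returns the first grid point attaining the maximum (ties break to the
#' earlier grid entry; for the elastic net the lambda path is computed once on
#' the full training portion, held fixed across folds, and traversed in path
#' order). A single-point grid is returned without any fitting.
#'
#' @param model_kind learner name.
#' @param X,y training portion.
#' @param n_folds inner fold count.
#' @param seed integer seed for the fold assignment.
#' @param grid optional `hyper_grid`; defaults to
#'   `make_hyperparameter_grid(model_kind)`.
#' @return named list of chosen hyperparameters.
#' @export
inner_cv_select <- function(model_kind, X, y, n_folds = 5L, seed = 1L,
                            grid = NULL) {
  grid <- grid %||% make_hyperparameter_grid(model_kind)
  if (model_kind == "rf" || (nrow(grid$grid) == 1 && model_kind != "enet")) {
    hp <- as.list(grid$grid[1, , drop = FALSE])
    return(c(hp, grid$fixed[setdiff(names(grid$fixed), "mtry_rule")]))
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_folds) stop("fewer training samples than inner folds")
  set.seed(substream_seed(seed, 17L))
  folds <- make_folds(n, n_folds)
  if (model_kind == "enet") {
    return(inner_cv_select_enet(X, y, folds, grid))
  }
  if (model_kind == "spls") {
    return(inner_cv_select_spls(X, y, folds, grid))
  }
  combos <- grid$grid
  scores <- matrix(NA_real_, nrow(combos), n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    if (stats::sd(y[tr]) == 0) next
    for (g in seq_len(nrow(combos))) {
      hp <- c(as.list(combos[g, , drop = FALSE]), grid$fixed)
      pred <- fit_predict(model_kind, hp, X[tr, , drop = FALSE], y[tr],
                          X[te, , drop = FALSE], seed = seed)
      scores[g, f] <- inner_r2(y[te], pred)
    }
  }
  mean_score <- rowMeans(scores, na.rm = TRUE)
  mean_score[is.nan(mean_score)] <- -Inf
  best <- which.max(mean_score)          # first max = earliest grid entry
  c(as.list(combos[best, , drop = FALSE]), grid$fixed)
}

# Elastic-net fast path: one lambda path per mixing value, computed on the
# whole training portion and reused in every fold, so the grid is the same
# (mixing x lambda) set for all folds.
inner_cv_select_enet <- function(X, y, folds, grid) {
  n_folds <- max(folds)
  mixings <- grid$grid$mixing
  best <- list(score = -Inf, mixing = mixings[1], lambda = NULL)
  for (r in mixings) {
    path_fit <- glmnet::glmnet(X, y, alpha = 1 - r,
                               nlambda = grid$fixed$n_lambda,
                               lambda.min.ratio = grid$fixed$lambda_min_ratio)
    lambda_path <- path_fit$lambda
    scores <- matrix(NA_real_, length(lambda_path), n_folds)
    for (f in seq_len(n_folds)) {
      tr <- folds != f; te <- !tr
      if (stats::sd(y[tr]) == 0) next
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = 1 - r,
                            lambda = lambda_path)
      preds <- stats::predict(fit, X[te, , drop = FALSE], s = lambda_path)
      scores[, f] <- apply(preds, 2, function(pp) inner_r2(y[te], pp))
    }
    ms <- rowMeans(scores, na.rm = TRUE)
    ms[is.nan(ms)] <- -Inf
    b <- which.max(ms)                   # path order = grid order
    if (ms[b] > best$score) {
      best <- list(score = ms[b], mixing = r, lambda = lambda_path[b])
    }
  }
  list(mixing = best$mixing, lambda = best$lambda)
}

# SPLS fast path: one K-path sweep per (eta, fold) scores every K at once.
# Scores are laid out in grid order (K fastest, as in expand.grid) so the
# first-maximum tie-break matches the generic loop.
inner_cv_select_spls <- function(X, y, folds, grid) {
  n_folds <- max(folds)
  etas <- unique(grid$grid$eta)
  K_max <- max(grid$grid$K)
  kappa <- grid$fixed$kappa
  scores <- matrix(NA_real_, nrow(grid$grid), n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    if (stats::sd(y[tr]) == 0) next
    for (j in seq_along(etas)) {
      path <- spls_fit_path(X[tr, , drop = FALSE], y[tr], K_max, etas[j], kappa)
      Xs_te <- scale(X[te, , drop = FALSE], center = path$mx, scale = path$sx)
      for (k in seq_len(K_max)) {
        pred <- as.numeric(Xs_te %*% path$betas[[k]] + path$my)
        row <- which(grid$grid$K == k & grid$grid$eta == etas[j])
        scores[row, f] <- inner_r2(y[te], pred)
      }
    }
  }
  ms <- rowMeans(scores, na.rm = TRUE)
  ms[is.nan(ms)] <- -Inf
  best <- which.max(ms)
  c(as.list(grid$grid[best, , drop = FALSE]), grid$fixed)
}

#' Repeated nested cross-validation benchmark for one metabolite
#'
#' For each repeat, samples are shuffled into `n_outer_folds` outer folds.
#' For each outer fold and learner, hyperparameters are selected by
#' `n_inner_folds`-fold cross-validation inside the training portion
#' (maximizing mean R-squared on the transformed scale), the learner is refit
#' on the full training portion, and the held-out fold is scored by
#' [fold_metrics()] on the back-transformed scale. Every (repeat, fold,
#' model) cell runs on its own seed substream, so the full record table is
#' bit-reproducible from `plan$seed` regardless of execution order.
#'
#' @param X predictor matrix (CLR scale), samples in rows.
#' @param y outcome vector on the transformed scale.
#' @param models character vector of learner names.
#' @param plan a [cv_plan()].
#' @param inverse transform kind for back-mapping before evaluation.
#' @param metabolite_id label recorded in the output.
#' @return data.frame of CV records: `metabolite`, `model`, `rep`, `fold`,
#'   `r2`, `scc`, `hyperparams` (compact string).
#' @export
nested_cv_evaluate <- function(X, y, models = c("rf", "svm_rbf", "enet", "spls"),
                               plan = cv_plan(), inverse = "identity",
                               metabolite_id = "metabolite") {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  rows <- vector("list", plan$n_repeats * plan$n_outer_folds * length(models))
  k <- 0L
  for (r in seq_len(plan$n_repeats)) {
    set.seed(substream_seed(plan$seed, 23L, r))
    folds <- make_folds(n, plan$n_outer_folds)
    for (f in seq_len(plan$n_outer_folds)) {
      tr <- folds != f; te <- !tr
      for (mi in seq_along(models)) {
        m <- models[mi]
        k <- k + 1L
        cell_seed <- substream_seed(plan$seed, r, f, mi)
        if (stats::sd(y[tr]) == 0) {
          rows[[k]] <- data.frame(metabolite = metabolite_id, model = m,
                                  rep = r, fold = f, r2 = NA_real_,
                                  scc = NA_real_, hyperparams = NA_character_)
          next
        }
        hp <- inner_cv_select(m, X[tr, , drop = FALSE], y[tr],
                              n_folds = plan$n_inner_folds, seed = cell_seed)
        pred <- fit_predict(m, hp, X[tr, , drop = FALSE], y[tr],
                            X[te, , drop = FALSE], seed = cell_seed)
        met <- fold_metrics(y[te], pred, inverse = inverse)
        rows[[k]] <- data.frame(metabolite = metabolite_id, model = m,
                                rep = r, fold = f, r2 = met$r2, scc = met$scc,
                                hyperparams = compact_hp(hp))
      }
    }
  }
  do.call(rbind, rows)
}

compact_hp <- function(hp) {
  hp <- hp[!vapply(hp, is.character, logical(1))]
  paste(sprintf("%s=%s", names(hp),
                vapply(hp, function(v) formatC(as.numeric(v), format = "g"),
                       character(1))),
        collapse = ";")
}
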