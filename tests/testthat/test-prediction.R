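test_that("hyperparameter grids have the documented shapes and values", {
  svm <- make_hyperparameter_grid("svm_rbf")
  expect_equal(n_combinations(svm), 110L)
  expect_setequal(unique(svm$grid$cost), 2^seq(-5, 15, 2))
  expect_setequal(unique(svm$grid$gamma), 2^seq(-15, 3, 2))

  enet <- make_hyperparameter_grid("enet")
  expect_equal(nrow(enet$grid), 11L)
  expect_equal(enet$fixed$n_lambda, 100L)
  expect_equal(n_combinations(enet), 1100L)

  spls <- make_hyperparameter_grid("spls")
  expect_equal(n_combinations(spls), 90L)
  expect_equal(spls$fixed$kappa, 0.5)
  expect_setequal(unique(spls$grid$K), 1:10)

  rf <- make_hyperparameter_grid("rf")
  expect_equal(n_combinations(rf), 1L)
  expect_equal(rf$grid$n_trees, 500)

  expect_error(make_hyperparameter_grid("boost"))
})

test_that("learners satisfy their basic contracts", {
  set.seed(61)
  X <- matrix(rnorm(60 * 6), 60, dimnames = list(NULL, paste0("g", 1:6)))

  # exact linear recovery by the elastic net at a small penalty
  y_lin <- 3 * X[, 2]
  pred <- fit_predict("enet", list(mixing = 0, lambda = 1e-4),
                      X[1:45, ], y_lin[1:45], X[46:60, ])
  expect_lt(max(abs(pred - y_lin[46:60]) / (abs(y_lin[46:60]) + 1e-8)), 1e-3)

  # random forest interpolates smooth signals in-sample
  y_sm <- sin(X[, 1]) + 0.5 * X[, 3]
  pred_rf <- fit_predict("rf", list(n_trees = 500), X, y_sm, X, seed = 2)
  expect_gt(cor(pred_rf, y_sm), 0.95)

  # every learner returns the constant for a constant outcome
  for (m in c("rf", "svm_rbf", "enet", "spls")) {
    hp <- switch(m, rf = list(n_trees = 100),
                 svm_rbf = list(cost = 1, gamma = 0.1),
                 enet = list(mixing = 0, lambda = 0.1),
                 spls = list(K = 2, eta = 0.5))
    expect_equal(fit_predict(m, hp, X[1:30, ], rep(2.5, 30), X[31:40, ]),
                 rep(2.5, 10))
  }

  # SPLS with a liberal threshold fits a linear signal well out-of-sample
  y_two <- X[, 1] - 2 * X[, 4] + rnorm(60, sd = 0.05)
  pred_sp <- fit_predict("spls", list(K = 3, eta = 0.5), X[1:45, ],
                         y_two[1:45], X[46:60, ])
  expect_gt(cor(pred_sp, y_two[46:60]), 0.95)
})

test_that("fold metrics reproduce hand arithmetic on the back-transformed scale", {
  m <- fold_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$r2, 1); expect_equal(m$scc, 1)

  m2 <- fold_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m2$r2, 0)

  m3 <- fold_metrics(c(1, 2, 3), c(3, 2, 1))
  expect_equal(m3$r2, -3); expect_equal(m3$scc, -1)

  # constant truth: undefined, recorded missing
  expect_true(is.na(fold_metrics(c(2, 2, 2), c(1, 2, 3))$r2))

  # back-transformation happens before scoring
  y <- c(1, 2, 3); yhat <- c(1.1, 1.9, 3.2)
  m4 <- fold_metrics(log1p(y), log1p(yhat), inverse = "log1p")
  expect_equal(m4$r2, 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
})

test_that("nested cross-validation partitions cleanly, counts records, and is reproducible", {
  set.seed(71)
  X <- matrix(rnorm(40 * 8), 40)
  y <- X[, 1] + rnorm(40, sd = 0.5)
  plan <- cv_plan(n_repeats = 1, n_outer_folds = 5, n_inner_folds = 3, seed = 9)

  rec <- nested_cv_evaluate(X, y, models = c("rf", "enet"), plan = plan)
  expect_equal(nrow(rec), 10L)           # 1 repeat x 5 folds x 2 models
  expect_setequal(unique(rec$model), c("rf", "enet"))
  expect_true(all(rec$scc >= -1 & rec$scc <= 1, na.rm = TRUE))
  expect_true(all(rec$r2 <= 1, na.rm = TRUE))

  # bit-identical reproduction from the same plan seed
  rec2 <- nested_cv_evaluate(X, y, models = c("rf", "enet"), plan = plan)
  expect_identical(rec, rec2)

  # outer folds partition the samples exactly
  set.seed(micrometab:::substream_seed(9, 23, 1))
  folds <- micrometab:::make_folds(40, 5)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 40)
  expect_true(all(table(folds) %in% c(8)))
})

test_that("an uninformative outcome cannot beat the fold-mean baseline on average", {
  set.seed(72)
  X <- matrix(rnorm(40 * 10), 40)
  y <- rnorm(40)                         # independent of X
  plan <- cv_plan(n_repeats = 2, n_outer_folds = 5, n_inner_folds = 3, seed = 4)
  rec <- nested_cv_evaluate(X, y, models = "enet", plan = plan)
  expect_lte(mean(rec$r2, na.rm = TRUE), 0)
})

test_that("elastic-net held-out accuracy increases with the signal-to-noise ratio", {
  res <- run_simulation_study(p_zero_grid = 0.5, snr_grid = c(0.5, 0.7, 3, 5),
                              n_datasets = 20, models = "enet",
                              n_samples = 60, n_taxa = 20,
                              tune_folds = 5, seed = 80)
  means <- tapply(res$r2, res$snr, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
})
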