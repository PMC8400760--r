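test_that("the hierarchical model recovers planted model effects", {
  eff <- c(rf = 0.1, svm_rbf = 0.2, enet = 0.3, spls = 0.4)
  rec <- make_hierarchical_records(eff, n_repeats = 100, n_folds = 5, seed = 91)
  fit <- suppressWarnings(fit_performance_model(rec, "r2"))
  got <- setNames(fit$summary$posterior_mean, fit$summary$model)
  expect_lt(max(abs(got[names(eff)] - eff)), 0.02)
  expect_true(all(fit$summary$ci_lower <= fit$summary$posterior_mean &
                    fit$summary$posterior_mean <= fit$summary$ci_upper))
})

test_that("identical statistic vectors give symmetric posteriors and boundary variance shrinks", {
  set.seed(92)
  base <- expand.grid(model = c("a", "b"), rep = 1:20, fold = 1:5,
                      stringsAsFactors = FALSE)
  stat <- rnorm(20 * 5, 0.2, 0.1)
  base$r2 <- stat[(base$rep - 1) * 5 + base$fold]   # same values for both models
  base$metabolite <- "m"
  fit <- suppressWarnings(fit_performance_model(base, "r2"))
  expect_lt(abs(diff(fit$summary$posterior_mean)), 0.01)

  # zero between-repeat variance: the repeat-scale posterior concentrates near 0
  eff <- c(a = 0.2, b = 0.3)
  rec0 <- make_hierarchical_records(eff, n_repeats = 40, n_folds = 5,
                                    sigma_repeat = 0, sigma_fold = 0.02,
                                    sigma = 0.05, seed = 93)
  fit0 <- suppressWarnings(fit_performance_model(rec0, "r2"))
  expect_lt(fit0$sigma_posterior_means["sigma_repeat"], 0.03)
})

test_that("degenerate performance records are rejected", {
  rec <- expand.grid(model = c("a", "b"), rep = 1:3, fold = 1:3,
                     stringsAsFactors = FALSE)
  rec$r2 <- 0.5
  rec$metabolite <- "m"
  expect_error(fit_performance_model(rec, "r2"), "identical")

  rec1 <- rec[rec$model == "a", ]
  rec1$r2 <- rnorm(nrow(rec1))
  expect_error(fit_performance_model(rec1, "r2"), "2 models")
})

test_that("predictability calls follow the credible-interval rules", {
  summ <- structure(list(
    summary = data.frame(model = c("rf", "svm_rbf"),
                         posterior_mean = c(0.1, 0.3),
                         ci_lower = c(-0.05, 0.01), ci_upper = c(0.2, 0.5)),
    metric = "r2", metabolite = "m1"), class = "posterior_summary")
  call <- classify_predictability(summ, "ci_above_zero")
  expect_true(call$predictable)
  expect_equal(call$best_model, "svm_rbf")

  summ$summary$ci_lower <- c(-0.05, -0.01)
  expect_false(classify_predictability(summ, "ci_above_zero")$predictable)

  expect_error(classify_predictability(summ, "scc_above_0.3"), "scc")
  summ$metric <- "scc"
  summ$summary$ci_lower <- c(0.0, 0.31)
  expect_true(classify_predictability(summ, "scc_above_0.3")$predictable)
  expect_true(classify_predictability(summ, "ci_above_zero")$predictable)

  # monotone: shifting every statistic upward never flips a predictable call
  shifted <- summ
  shifted$summary[, c("posterior_mean", "ci_lower", "ci_upper")] <-
    shifted$summary[, c("posterior_mean", "ci_lower", "ci_upper")] + 0.1
  expect_true(classify_predictability(shifted, "scc_above_0.3")$predictable)
})

test_that("Borda aggregation awards 4/3/2/1, shares ties, and conserves points", {
  df <- rbind(
    data.frame(metabolite = "m1", model = c("svm", "rf", "enet", "spls"),
               posterior_mean = c(0.4, 0.3, 0.2, 0.1)),
    data.frame(metabolite = "m2", model = c("svm", "enet", "rf", "spls"),
               posterior_mean = c(0.5, 0.4, 0.3, 0.2)))
  tab <- borda_aggregate(df)
  pts <- setNames(tab$points, tab$model)
  expect_equal(pts[["svm"]], 8)
  expect_equal(pts[["rf"]], 5)
  expect_equal(pts[["enet"]], 5)
  expect_equal(pts[["spls"]], 2)
  expect_equal(sum(tab$points), 20)

  # full ties share 2.5 each
  df_tie <- data.frame(metabolite = rep(c("m1", "m2", "m3"), each = 4),
                       model = rep(c("a", "b", "c", "d"), 3),
                       posterior_mean = 0.2)
  tab_tie <- borda_aggregate(df_tie)
  expect_true(all(tab_tie$points == 2.5 * 3))

  # one metabolite: a permutation of 4/3/2/1
  one <- df[df$metabolite == "m1", ]
  expect_setequal(borda_aggregate(one)$points, c(4, 3, 2, 1))

  # a metabolite missing a model is skipped with a warning
  expect_warning(tab_miss <- borda_aggregate(rbind(df, data.frame(
    metabolite = "m3", model = "svm", posterior_mean = 1))), "skipped")
  expect_equal(sum(tab_miss$points), 20)
})
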