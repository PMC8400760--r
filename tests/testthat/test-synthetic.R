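test_that("community generation hits its sparsity target and closes rows", {
  ft0 <- generate_community(20, 10, sparsity = 0, seed = 1)
  expect_true(all(ft0$values > 0))
  expect_equal(unname(rowSums(ft0$values)), rep(1, 20), tolerance = 1e-12)

  ft <- generate_community(100, 50, sparsity = 0.5, seed = 2)
  expect_lt(abs(mean(ft$values == 0) - 0.5), 0.05)
  expect_equal(unname(rowSums(ft$values)), rep(1, 100), tolerance = 1e-12)
})

test_that("row bootstrap only emits rows of the source matrix", {
  ft <- generate_community(5, 6, sparsity = 0.2, seed = 3)
  boot <- bootstrap_community(ft, n = 5, seed = 4)
  in_source <- apply(boot$values, 1, function(r)
    any(apply(ft$values, 1, function(s) all(abs(r - s) < 1e-15))))
  expect_true(all(in_source))
  # reproducible by seed
  boot2 <- bootstrap_community(ft, n = 5, seed = 4)
  expect_equal(boot$values, boot2$values)
})

test_that("the linear simulator enforces the SNR identity and sparsity pattern", {
  set.seed(5)
  X <- matrix(rnorm(50 * 20), 50)
  sim <- simulate_linear_metabolite(X, p_zero = 0.5, snr = 3, seed = 6)
  signal <- sim$beta0 + as.numeric(X %*% sim$beta)
  expect_equal(sd(signal) / sim$epsilon_sd, 3, tolerance = 1e-10)
  expect_equal(sim$Y, signal + sim$epsilon)
  expect_equal(sim$beta0, 6 / sqrt(10))

  # p_zero = 1: fallback noise scale with a warning
  expect_warning(sim1 <- simulate_linear_metabolite(X, 1, 3, seed = 7),
                 "sigma_eps")
  expect_true(sim1$degenerate)
  expect_equal(sim1$epsilon_sd, 1)
  expect_true(all(sim1$beta == 0))

  # realized nonzero fraction over many draws at p_zero = 0.95
  frac <- mean(vapply(1:1000, function(i) {
    mean(suppressWarnings(
      simulate_linear_metabolite(X[1:3, ], 0.95, 1, seed = i))$beta != 0)
  }, numeric(1)))
  expect_lt(abs(frac - 0.05), 0.015)
})

test_that("the richness shuffle preserves per-sample multisets, sums and richness", {
  m <- rbind(c(3, 0, 2, 0), c(1, 1, 0, 5))
  sh <- richness_shuffle(m, seed = 8)
  for (i in 1:2) {
    expect_equal(sort(sh[i, ]), sort(m[i, ]))
  }
  expect_equal(rowSums(sh), rowSums(m))
  expect_equal(rowSums(sh > 0), rowSums(m > 0))

  # single column: identity
  expect_equal(richness_shuffle(matrix(1:3, 3), seed = 9), matrix(1:3, 3))

  # each ordering of a 3-vector appears uniformly
  counts <- table(vapply(1:6000, function(i)
    paste(richness_shuffle(matrix(c(1, 2, 3), 1), seed = i), collapse = ""),
    character(1)))
  expect_equal(length(counts), 6L)
  expect_true(all(abs(counts / 6000 - 1 / 6) < 0.02))

  # matches the invariants of the reference richness null model
  comm <- matrix(rpois(30, 4), 5)
  ref <- picante::randomizeMatrix(comm, null.model = "richness")
  expect_equal(rowSums(ref > 0), rowSums(comm > 0))   # same preserved quantity
  ours <- richness_shuffle(comm, seed = 10)
  expect_equal(rowSums(ours > 0), rowSums(comm > 0))
})

test_that("random trees have binary shape and are seed-deterministic", {
  t2 <- random_tree(2, seed = 11)
  expect_equal(ape::Ntip(t2), 2L)
  expect_equal(nrow(t2$edge), 2L)

  t8 <- random_tree(8, seed = 12)
  expect_equal(ape::Ntip(t8), 8L)
  expect_equal(nrow(t8$edge), 14L)
  expect_true(ape::is.rooted(t8))
  expect_true(all(t8$edge.length >= 0))

  expect_equal(ape::write.tree(random_tree(8, seed = 13)),
               ape::write.tree(random_tree(8, seed = 13)))
})

test_that("the simulation study emits the expected rows and reproduces itself", {
  res <- run_simulation_study(p_zero_grid = 0.5, snr_grid = 3, n_datasets = 3,
                              models = c("rf", "enet"), n_samples = 30,
                              n_taxa = 10, tune_folds = 5, seed = 14)
  expect_equal(nrow(res), 6L)
  expect_setequal(unique(res$model), c("rf", "enet"))
  expect_true(all(res$arm == "positive"))
  expect_true(all(res$scc >= -1 & res$scc <= 1))

  res2 <- run_simulation_study(p_zero_grid = 0.5, snr_grid = 3, n_datasets = 3,
                               models = c("rf", "enet"), n_samples = 30,
                               n_taxa = 10, tune_folds = 5, seed = 14)
  expect_identical(res, res2)
})

test_that("elastic net recovers the planted coefficient support in the sparse regime", {
  jaccards <- c()
  d <- 0
  while (length(jaccards) < 5 && d < 25) {
    d <- d + 1
    base <- generate_community(60, 30, 0.3, seed = 15)
    boot <- bootstrap_community(base, 60, seed = 100 + d)
    Xc <- micrometab:::community_to_clr(boot$values)
    sim <- suppressWarnings(
      simulate_linear_metabolite(Xc, p_zero = 0.95, snr = 5, seed = 200 + d))
    if (all(sim$beta == 0)) next
    hp <- inner_cv_select("enet", Xc, sim$Y, n_folds = 5, seed = 300 + d)
    fit <- glmnet::glmnet(Xc, sim$Y, alpha = 1 - hp$mixing,
                          lambda = hp$lambda)
    est <- which(as.numeric(coef(fit))[-1] != 0)
    truth <- which(sim$beta != 0)
    jaccards <- c(jaccards,
                  length(intersect(est, truth)) / length(union(est, truth)))
  }
  expect_gte(length(jaccards), 5)
  expect_gt(mean(jaccards), 0.3)
})
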