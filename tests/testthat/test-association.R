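test_that("Spearman screening recovers monotone pairs and applies BH jointly", {
  set.seed(41)
  x <- matrix(rnorm(30), ncol = 1)
  z <- cbind(exp(x[, 1]), rnorm(30))        # monotone in x, then noise
  am <- spearman_association_matrix(x, z)
  expect_equal(am$rho[1, 1], 1)
  expect_true(all(am$q_value >= am$p_value - 1e-12, na.rm = TRUE))
  expect_true(all(am$q_value <= 1, na.rm = TRUE))

  # constant column is recorded missing and excluded from the BH family
  zc <- cbind(z, 5)
  am2 <- spearman_association_matrix(x, zc)
  expect_true(all(is.na(am2$rho[, 3])))
  expect_equal(sum(!is.na(am2$q_value)), 2)
})

test_that("BH q-values follow the step-up hand computation and stay monotone in p", {
  # the package applies p.adjust over the pooled pair family; check the
  # documented example through the full matrix interface
  set.seed(42)
  n <- 24
  base <- rnorm(n)
  # build 4 taxon columns whose correlations with one metabolite produce
  # increasing p-values, then verify monotonicity of q in p
  X <- sapply(c(0.9, 0.7, 0.5, 0.3), function(s) s * base + rnorm(n, sd = 1))
  am <- spearman_association_matrix(X, matrix(base, ncol = 1))
  p <- am$p_value[, 1]; q <- am$q_value[, 1]
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # direct check of the hand example via the same adjustment rule
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
})

test_that("penalized decomposition honors its constraints and degenerate cases", {
  set.seed(51)
  # p = q = 1: no sparsity possible, rho_1 is |Pearson correlation|
  x <- scale(rnorm(40)); z <- scale(-2 * x + rnorm(40))
  f1 <- scca_fit(x, z, 1, 1)
  expect_equal(f1$rho_1, abs(cor(x, z)[1]), tolerance = 1e-10)

  # constraints hold at convergence for random penalties
  for (i in 1:10) {
    X <- scale(matrix(rnorm(30 * 7), 30)); Z <- scale(matrix(rnorm(30 * 5), 30))
    cu <- runif(1, 1, sqrt(7)); cv <- runif(1, 1, sqrt(5))
    f <- scca_fit(X, Z, cu, cv)
    expect_lte(sqrt(sum(f$u^2)), 1 + 1e-8)
    expect_lte(sqrt(sum(f$v^2)), 1 + 1e-8)
    expect_lte(sum(abs(f$u)), cu + 1e-6)
    expect_lte(sum(abs(f$v)), cv + 1e-6)
    expect_true(abs(f$rho_1) <= 1 + 1e-12)
  }

  # all-zero cross-product
  f0 <- scca_fit(matrix(0, 10, 3), scale(matrix(rnorm(30), 10)), 1.2, 1.2)
  expect_equal(f0$rho_1, 0)
  expect_length(f0$selected_taxa, 0)

  expect_error(scca_fit(scale(matrix(rnorm(20), 10)), scale(matrix(rnorm(20), 10)),
                        c_u = 0.5), "c_u")
})

test_that("support size shrinks with the L1 budget and rho is exchange-symmetric", {
  set.seed(52)
  pair <- make_latent_factor_pair(n = 50, p = 8, q = 8, seed = 52)
  Xc <- scale(pair$X); Zc <- scale(pair$Z)
  budgets <- seq(sqrt(8), 1, length.out = 6)
  sizes <- sapply(budgets, function(cc) length(scca_fit(Xc, Zc, cc, cc)$selected_taxa))
  expect_true(all(diff(sizes) <= 0))

  f_xy <- scca_fit(Xc, Zc, 2, 2)
  f_yx <- scca_fit(Zc, Xc, 2, 2)
  expect_equal(abs(f_yx$rho_1), abs(f_xy$rho_1), tolerance = 1e-6)
})

test_that("sCCA recovers a planted shared factor and its loaded features", {
  pair <- make_latent_factor_pair(n = 80, p = 10, q = 10, n_loaded = 3,
                                  noise = 0.25, seed = 53)
  f <- scca_fit(scale(pair$X), scale(pair$Z), 2, 2)
  expect_gt(abs(f$rho_1), 0.9)
  expect_true(all(paste0("t", pair$loaded) %in% f$selected_taxa))
  expect_true(all(paste0("m", pair$loaded) %in% f$selected_metabolites))
})

test_that("permutation tuning selects sparse solutions and degenerate grids pass through", {
  # single-point grid returned unconditionally
  X <- scale(matrix(rnorm(60), 20)); Z <- scale(matrix(rnorm(60), 20))
  expect_equal(scca_tune(X, Z, penalty_grid = 1.5)$c_u, 1.5)

  # one strongly correlated column pair embedded in noise: small supports
  set.seed(54)
  n <- 60
  shared <- rnorm(n)
  Xs <- cbind(shared + rnorm(n, sd = 0.1), matrix(rnorm(n * 7), n))
  Zs <- cbind(shared + rnorm(n, sd = 0.1), matrix(rnorm(n * 7), n))
  tuned <- scca_tune(scale(Xs), scale(Zs), n_perm_tune = 25, seed = 9)
  fit <- scca_fit(scale(Xs), scale(Zs), tuned$c_u, tuned$c_v)
  expect_lte(length(fit$selected_taxa), 3)
  expect_true(fit$u[1] != 0)   # the planted column is selected
})

test_that("inference wires the bootstrap interval and richness permutation consistently", {
  pair <- make_latent_factor_pair(n = 50, p = 8, q = 8, n_loaded = 2,
                                  noise = 0.3, seed = 55)
  inf <- scca_inference(pair$X, pair$Z, c_u = 2, c_v = 2,
                        n_boot = 500, n_perm = 200, seed = 3)
  expect_gt(inf$ci_95[1], 0)                 # CI excludes 0 for real signal
  expect_lte(inf$p_perm, 0.05)
  # the reported p honors the add-one estimator over the stored draws
  expect_equal(inf$p_perm,
               (1 + sum(inf$perm_rho >= inf$rho_1)) / (length(inf$perm_rho) + 1))
  expect_equal(length(inf$boot_rho), 500)
})
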