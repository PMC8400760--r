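# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-derivations (brute-force walks, closed forms,
# textbook eigenproblems) kept separate from the package's own code paths.

# Brute-force weighted (normalized) UniFrac: for every edge, find the
# descendant tip set by recursive descent, then
#   d = sum_b l_b |p_b - q_b| / sum_b l_b (p_b + q_b).
# Equals generalized UniFrac at alpha = 1.
brute_force_weighted_unifrac <- function(p_profile, q_profile, tree) {
  tips_below <- function(node) {
    n_tip <- length(tree$tip.label)
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_below(tree$edge[e, 2])
    p <- sum(p_profile[tips]); q <- sum(q_profile[tips])
    l <- tree$edge.length[e]
    num <- num + l * abs(p - q)
    den <- den + l * (p + q)
  }
  num / den
}

# Classical first canonical correlation via the generalized eigenproblem
# rho^2 = largest eigenvalue of Sxx^-1 Sxy Szz^-1 Szx.
classical_cca_rho1 <- function(X, Z) {
  Sxx <- stats::cov(X); Szz <- stats::cov(Z); Sxz <- stats::cov(X, Z)
  M <- solve(Sxx, Sxz) %*% solve(Szz, t(Sxz))
  sqrt(max(Re(eigen(M)$values)))
}

# Paired matrices whose blocks are exactly column-whitened (centered,
# orthogonalized, unit-sd): within-block sample correlation is the identity,
# the regime in which penalty-free PMD and classical CCA coincide.
make_whitened_pair <- function(n, p, coupling = 0.6, seed = 1) {
  set.seed(seed)
  whiten <- function(M) {
    M <- scale(M, scale = FALSE)
    scale(qr.Q(qr(M)))
  }
  X <- whiten(matrix(rnorm(n * p), n))
  Z <- whiten(coupling * X + matrix(rnorm(n * p), n))
  list(X = X, Z = Z)
}

# Two matrices driven by one shared latent factor plus small noise.
make_latent_factor_pair <- function(n = 60, p = 10, q = 10, n_loaded = 3,
                                    noise = 0.3, seed = 1) {
  set.seed(seed)
  f <- rnorm(n)
  X <- matrix(rnorm(n * p, sd = noise), n)
  Z <- matrix(rnorm(n * q, sd = noise), n)
  X[, seq_len(n_loaded)] <- X[, seq_len(n_loaded)] + f
  Z[, seq_len(n_loaded)] <- Z[, seq_len(n_loaded)] + f
  colnames(X) <- paste0("t", seq_len(p)); colnames(Z) <- paste0("m", seq_len(q))
  list(X = X, Z = Z, loaded = seq_len(n_loaded))
}

# Balanced-design fold-level statistics drawn from the hierarchical model.
make_hierarchical_records <- function(effects, n_repeats, n_folds,
                                      sigma_repeat = 0.05, sigma_fold = 0.05,
                                      sigma = 0.05, seed = 1) {
  set.seed(seed)
  models <- names(effects)
  rec <- expand.grid(model = models, rep = seq_len(n_repeats),
                     fold = seq_len(n_folds), stringsAsFactors = FALSE)
  a <- rnorm(n_repeats, 0, sigma_repeat)
  b <- matrix(rnorm(n_repeats * n_folds, 0, sigma_fold), n_repeats)
  rec$r2 <- effects[rec$model] + a[rec$rep] + b[cbind(rec$rep, rec$fold)] +
    rnorm(nrow(rec), 0, sigma)
  rec$scc <- rec$r2
  rec$metabolite <- "m1"
  rec
}

# Small paired taxa/metabolite fixture on disk for CLI tests.
write_cli_fixture <- function(dir, n = 12, p = 6, q = 4, seed = 7) {
  set.seed(seed)
  taxa <- matrix(rpois(n * p, lambda = 40), n,
                 dimnames = list(paste0("s", seq_len(n)), paste0("asv", seq_len(p))))
  metab <- matrix(round(rexp(n * q, 0.2), 3), n,
                  dimnames = list(paste0("s", seq_len(n)), paste0("met", seq_len(q))))
  taxa_path <- file.path(dir, "taxa.tsv")
  metab_path <- file.path(dir, "metab.tsv")
  write_feature_table(feature_table(taxa), taxa_path)
  write_feature_table(feature_table(metab), metab_path)
  tax_map <- data.frame(asv = paste0("asv", seq_len(p)),
                        genus = paste0("g", rep(seq_len(ceiling(p / 2)), length.out = p)))
  tax_path <- file.path(dir, "taxonomy.tsv")
  utils::write.table(tax_map, tax_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(taxa = taxa_path, metab = metab_path, taxonomy = tax_path)
}

md5_of <- function(paths) unname(tools::md5sum(paths))
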