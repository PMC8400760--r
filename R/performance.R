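#' Bayesian hierarchical model of fold-level performance
#'
#' For one metabolite and one evaluation metric, models the fold-level
#' statistics as
#' `stat[m, r, f] = mu + beta_m + a_r + b_{r,f} + e`, with random intercepts
#' `a_r ~ N(0, sigma_repeat^2)` varying among repeats, `b_{r,f} ~ N(0,
#' sigma_fold^2)` for folds within repeats (shared across models evaluated on
#' the same fold), and Gaussian error — i.e. `stat ~ model + (1 | rep) +
#' (1 | rep:fold)` with identity link. Weakly informative priors: Normal(0,
#' sd 10) on the intercept and model effects, Exponential(1) on the three
#' scale parameters. The posterior is sampled by MCMC (4 chains, 1000
#' adaptation/warmup + 1000 kept draws each); per-model summaries are the
#' posterior mean and central 95% credible interval of `mu + beta_m`, and the
#' Gelman-Rubin statistic is reported with a warning above 1.01.
#'
#' @param records data.frame of CV records for one metabolite (columns
#'   `model`, `rep`, `fold`, and the metric column).
#' @param metric `"r2"` or `"scc"`.
#' @param n_chains,n_warmup,n_draws MCMC settings.
#' @param quiet suppress sampler progress output.
#' @return a `posterior_summary`: data.frame `summary` (model,
#'   posterior_mean, ci_lower, ci_upper), `metric`, `metabolite`,
#'   `diagnostics` (max_rhat, chains, draws).
#' @export
fit_performance_model <- function(records, metric = c("r2", "scc"),
                                  n_chains = 4L, n_warmup = 1000L,
                                  n_draws = 1000L, quiet = TRUE) {
  metric <- match.arg(metric)
  y <- records[[metric]]
  keep <- !is.na(y)
  records <- records[keep, , drop = FALSE]
  y <- y[keep]
  models <- sort(unique(as.character(records$model)))
  if (length(models) < 2) stop("at least 2 models are required")
  if (length(unique(records$rep)) < 2 || length(unique(paste(records$rep, records$fold))) < 4)
    stop("at least 2 repeats with 2 folds each are required")
  if (stats::sd(y) == 0)
    stop("all statistics are identical; the likelihood is degenerate ",
         "(jitter the records or supply more folds)")
  model_idx <- match(as.character(records$model), models)
  rep_idx <- match(records$rep, sort(unique(records$rep)))
  cell <- paste(records$rep, records$fold, sep = ":")
  cell_idx <- match(cell, unique(cell))

  jags_code <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu + beta[model_idx[i]] + a[rep_idx[i]] + b[cell_idx[i]], tau_e)
  }
  mu ~ dnorm(0, 0.01)
  beta[1] <- 0
  for (m in 2:M) { beta[m] ~ dnorm(0, 0.01) }
  for (r in 1:R) { a[r] ~ dnorm(0, tau_a) }
  for (c in 1:C) { b[c] ~ dnorm(0, tau_b) }
  sigma_e ~ dexp(1); tau_e <- 1 / (sigma_e * sigma_e)
  sigma_repeat ~ dexp(1); tau_a <- 1 / (sigma_repeat * sigma_repeat)
  sigma_fold ~ dexp(1); tau_b <- 1 / (sigma_fold * sigma_fold)
  for (m in 1:M) { model_mean[m] <- mu + beta[m] }
}"
  data_list <- list(y = y, N = length(y), M = length(models),
                    R = max(rep_idx), C = max(cell_idx),
                    model_idx = model_idx, rep_idx = rep_idx,
                    cell_idx = cell_idx)
  inits <- lapply(seq_len(n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1000L + ch)
  })
  run <- function() {
    jm <- rjags::jags.model(textConnection(jags_code), data = data_list,
                            inits = inits, n.chains = n_chains,
                            n.adapt = n_warmup, quiet = quiet)
    rjags::coda.samples(jm, c("model_mean", "sigma_e", "sigma_repeat",
                              "sigma_fold"),
                        n.iter = n_draws, thin = 1)
  }
  samples <- if (quiet) {
    tmp <- tempfile(); con <- file(tmp, open = "wt")
    sink(con); on.exit({ sink(); close(con); unlink(tmp) }, add = TRUE)
    run()
  } else run()

  draws <- do.call(rbind, lapply(samples, as.matrix))
  mm_cols <- paste0("model_mean[", seq_along(models), "]")
  summ <- data.frame(
    model = models,
    posterior_mean = colMeans(draws[, mm_cols, drop = FALSE]),
    ci_lower = apply(draws[, mm_cols, drop = FALSE], 2,
                     stats::quantile, probs = 0.025),
    ci_upper = apply(draws[, mm_cols, drop = FALSE], 2,
                     stats::quantile, probs = 0.975),
    row.names = NULL)
  rhat <- tryCatch(
    max(coda::gelman.diag(samples, autoburnin = FALSE,
                          multivariate = FALSE)$psrf[, 1]),
    error = function(e) NA_real_)
  if (!is.na(rhat) && rhat > 1.01)
    warning(sprintf("convergence statistic %.3f exceeds 1.01", rhat))
  structure(list(summary = summ, metric = metric,
                 metabolite = as.character(records$metabolite[1] %||% "metabolite"),
                 sigma_posterior_means = colMeans(
                   draws[, c("sigma_e", "sigma_repeat", "sigma_fold")]),
                 diagnostics = list(max_rhat = rhat, chains = n_chains,
                                    draws = n_draws * n_chains)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior_summary (%s, metric %s; max Rhat %.3f)\n",
              x$metabolite, x$metric, x$diagnostics$max_rhat))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Call a metabolite predictable or not
#'
#' Judged on the best model (highest posterior mean): under
#' `"ci_above_zero"`, predictable when its 95% credible interval lower bound
#' exceeds 0; under the more stringent `"scc_above_0.3"` (valid only for the
#' Spearman metric), when the lower bound exceeds 0.3.
#'
#' @param summary a `posterior_summary`.
#' @param rule `"ci_above_zero"` or `"scc_above_0.3"`.
#' @return a `predictability_call`: list with `metabolite`, `metric`,
#'   `predictable`, `rule`, `best_model`.
#' @export
classify_predictability <- function(summary,
                                    rule = c("ci_above_zero", "scc_above_0.3")) {
  rule <- match.arg(rule)
  if (rule == "scc_above_0.3" && summary$metric != "scc")
    stop("rule scc_above_0.3 applies only to the scc metric")
  best <- summary$summary[which.max(summary$summary$posterior_mean), ]
  cutoff <- if (rule == "ci_above_zero") 0 else 0.3
  structure(list(metabolite = summary$metabolite, metric = summary$metric,
                 predictable = best$ci_lower > cutoff, rule = rule,
                 best_model = best$model),
            class = "predictability_call")
}

#' Borda rank aggregation of model performance across metabolites
#'
#' Per metabolite, models are ranked by posterior mean (descending) and
#' awarded 4/3/2/1 points from first to fourth; exactly tied posterior means
#' share the mean of the contested points, so every metabolite always
#' contributes 10 points in total. Metabolites missing any model are skipped
#' with a warning.
#'
#' @param summaries either a list of `posterior_summary` objects or a
#'   data.frame with columns `metabolite`, `model`, `posterior_mean`.
#' @param metric label recorded in the output.
#' @return a `borda_table`: data.frame `model`, `points`, sorted by points
#'   descending, with attributes `metric` and `n_metabolites`.
#' @export
borda_aggregate <- function(summaries, metric = "r2") {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(summaries, function(s) {
      cbind(metabolite = s$metabolite, s$summary[, c("model", "posterior_mean")])
    }))
  }
  models <- sort(unique(summaries$model))
  M <- length(models)
  pts <- stats::setNames(numeric(M), models)
  n_used <- 0L
  for (met in unique(summaries$metabolite)) {
    block <- summaries[summaries$metabolite == met, ]
    if (!setequal(block$model, models) || nrow(block) != M) {
      warning("metabolite ", met, " is missing models; skipped")
      next
    }
    ranks <- rank(-block$posterior_mean, ties.method = "average")
    pts[block$model] <- pts[block$model] + (M + 1 - ranks)
    n_used <- n_used + 1L
  }
  total_expected <- n_used * M * (M + 1) / 2
  stopifnot(abs(sum(pts) - total_expected) < 1e-8)
  out <- data.frame(model = names(pts), points = as.numeric(pts))
  out <- out[order(-out$points, out$model), ]
  rownames(out) <- NULL
  structure(out, metric = metric, n_metabolites = n_used,
            class = c("borda_table", "data.frame"))
}
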