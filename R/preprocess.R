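#' Filter ASVs, aggregate to genus, and convert to proportions
#'
#' The compositional preprocessing pipeline for amplicon count tables, applied
#' in a fixed order: (1) drop ASVs whose prevalence — the fraction of samples
#' with a raw value > 0 — is below `prevalence_threshold` (retention is
#' inclusive at exactly the threshold); (2) add `pseudocount` to every
#' remaining cell; (3) sum ASVs within genus; (4) divide each row by its total
#' so rows are relative proportions; (5) drop genera whose mean proportion
#' across samples is strictly below `mean_abundance_threshold`, then
#' re-normalize rows to sum to one (keeping the result a closed composition so
#' the centered log-ratio transform stays well defined).
#'
#' ASVs without a genus assignment are pooled into the sentinel genus
#' `"unclassified"` rather than discarded, conserving reads.
#'
#' @param table [feature_table] of non-negative ASV counts.
#' @param taxonomy named character vector (or data.frame with a `genus`
#'   column rownamed by ASV) mapping ASV ids to genus labels.
#' @param config an [analysis_config]; supplies the thresholds and
#'   pseudocount.
#' @return a [feature_table] of genus-level relative proportions, rows summing
#'   to one, with a `filter_report` attribute tabulating feature counts after
#'   each step.
#' @export
filter_and_aggregate_taxa <- function(table, taxonomy, config = analysis_config()) {
  stopifnot(inherits(table, "feature_table"))
  counts <- table$values
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.data.frame(taxonomy)) {
    taxonomy <- stats::setNames(as.character(taxonomy$genus), rownames(taxonomy))
  }
  # 1. prevalence filter on raw counts (> 0), inclusive at the threshold
  prevalence <- colMeans(counts > 0)
  keep <- prevalence >= config$prevalence_threshold
  counts <- counts[, keep, drop = FALSE]
  n_after_prevalence <- ncol(counts)
  if (n_after_prevalence == 0) stop("no ASV passes the prevalence filter")
  # 2. pseudocount
  counts <- counts + config$pseudocount
  # 3. genus aggregation (unassigned ASVs pooled into a sentinel genus)
  genus <- taxonomy[colnames(counts)]
  genus[is.na(genus) | genus == ""] <- "unclassified"
  agg <- t(rowsum(t(counts), group = genus))
  # rowsum orders groups by sort(unique(genus)); keep that deterministic order
  # 4. close to proportions
  totals <- rowSums(agg)
  if (any(totals == 0)) {
    stop("sample(s) with zero total after aggregation: ",
         paste(rownames(agg)[totals == 0], collapse = ", "))
  }
  props <- agg / totals
  # 5. mean-abundance filter (strictly below the threshold is dropped),
  #    then re-close
  keep_genus <- colMeans(props) >= config$mean_abundance_threshold
  props <- props[, keep_genus, drop = FALSE]
  if (ncol(props) == 0) stop("no genus passes the mean-abundance filter")
  props <- props / rowSums(props)
  out <- feature_table(props)
  attr(out, "filter_report") <- data.frame(
    step = c("input_asvs", "after_prevalence_filter", "genera_after_aggregation",
             "genera_after_abundance_filter"),
    n_features = c(ncol(table$values), n_after_prevalence,
                   ncol(agg), ncol(props)))
  out
}

#' Centered log-ratio transform
#'
#' Per sample (row), `clr_j = log(x_j) - mean_k log(x_k)`. Output rows sum to
#' zero and the transform is invariant to positive rescaling of a row, which
#' is what makes it suitable for compositional data.
#'
#' @param x a [feature_table] or numeric matrix of strictly positive values
#'   (the preprocessing pseudocount guarantees positivity).
#' @return a numeric matrix of the same shape, rows summing to 0.
#' @export
clr_transform <- function(x) {
  m <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  if (any(m <= 0)) stop("clr_transform requires strictly positive values; ",
                        "first offending cell at index ", which(m <= 0)[1])
  lx <- log(m)
  sweep(lx, 1, rowMeans(lx), "-")
}

#' Metabolite variance-stabilizing transforms and their inverses
#'
#' Targeted concentrations use `log1p` (`y = log(x + 1)`, inverse
#' `exp(y) - 1`); untargeted spectral-bin relative intensities, which live in
#' `[0, 1]`, use the arcsine square root (`y = asin(sqrt(x))`, inverse
#' `sin(y)^2`). Both are exact bijections on their domains, so held-out
#' predictions can be mapped back to the original concentration scale before
#' evaluation. `identity` passes values through.
#'
#' @param x numeric vector/matrix (or [feature_table]) to transform.
#' @param kind one of `"log1p"`, `"arcsine_sqrt"`, `"identity"`.
#' @return transformed numeric object of the same shape.
#' @export
transform_metabolites <- function(x, kind = c("log1p", "arcsine_sqrt", "identity")) {
  kind <- match.arg(kind)
  m <- if (inherits(x, "feature_table")) x$values else x
  switch(kind,
    log1p = {
      if (any(m < 0)) stop("log1p transform requires values >= 0")
      log1p(m)
    },
    arcsine_sqrt = {
      if (any(m < 0 | m > 1)) {
        bad <- m[m < 0 | m > 1][1]
        stop("arcsine_sqrt transform requires values in [0, 1]; got ", bad)
      }
      asin(sqrt(m))
    },
    identity = m)
}

#' @rdname transform_metabolites
#' @param y transformed values to map back.
#' @export
inverse_transform_metabolites <- function(y, kind = c("log1p", "arcsine_sqrt", "identity")) {
  kind <- match.arg(kind)
  switch(kind,
    log1p = expm1(y),
    arcsine_sqrt = sin(y)^2,
    identity = y)
}
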