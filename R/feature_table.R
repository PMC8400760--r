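#' Construct a feature table
#'
#' The central container of the package: a non-negative samples x features
#' matrix with unique, ordered sample and feature identifiers, optionally
#' carrying per-feature metadata (taxonomy ranks for microbial tables, or
#' metabolite identity and assay type for metabolomic tables).
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param sample_ids character vector of unique sample labels; defaults to
#'   `rownames(values)`.
#' @param feature_ids character vector of unique feature labels; defaults to
#'   `colnames(values)`.
#' @param feature_meta optional data.frame keyed by feature id (rownames) with
#'   feature annotations (e.g. a `genus` column, or `assay` in
#'   `c("targeted", "untargeted")`).
#' @param allow_negative logical; transformed tables (e.g. CLR output) may hold
#'   negative values, raw abundance tables may not.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          feature_ids = colnames(values),
                          feature_meta = NULL, allow_negative = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match row count")
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length does not match column count")
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  dup_f <- feature_ids[duplicated(feature_ids)]
  if (length(dup_f)) stop("duplicate feature id(s): ", paste(unique(dup_f), collapse = ", "))
  if (anyNA(values)) stop("missing cells are not allowed in a feature table")
  if (!allow_negative && any(values < 0))
    stop("negative value in feature table at ",
         paste(which(values < 0)[1], collapse = ""))
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, feature_meta = feature_meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features\n",
              length(x$sample_ids), length(x$feature_ids)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Read a delimited feature table
#'
#' Reads a TSV (or other single-character-delimited) text file with one header
#' row and one id column into a [feature_table] in samples x features
#' orientation. Input ordering of rows and columns is preserved.
#'
#' @param path path to a delimited text file.
#' @param orientation `"samples-in-rows"` (default) when rows are samples and
#'   columns are features, `"features-in-rows"` for the transposed layout.
#' @param sep field delimiter, default tab.
#' @return a [feature_table].
#' @export
read_feature_table <- function(path,
                               orientation = c("samples-in-rows", "features-in-rows"),
                               sep = "\t") {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected an id column plus at least one data column")
  ids <- raw[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id(s) in first column: ",
                        paste(unique(dup), collapse = ", "))
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1L,
                dimnames = list(ids, colnames(raw)[-1]))
  for (j in seq_len(ncol(mat))) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) & !(raw[[j + 1L]] %in% c("NA", "NaN")))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1], colnames(mat)[j], raw[[j + 1L]][bad[1]]))
    if (anyNA(v)) stop(sprintf("missing value at row %d, column '%s'",
                               which(is.na(v))[1], colnames(mat)[j]))
    neg <- which(v < 0)
    if (length(neg))
      stop(sprintf("negative value at row %d, column '%s': %s",
                   neg[1], colnames(mat)[j], v[neg[1]]))
    mat[, j] <- v
  }
  if (orientation == "features-in-rows") mat <- t(mat)
  feature_table(mat)
}

#' Write a feature table as TSV
#'
#' Inverse of [read_feature_table()] (samples-in-rows orientation): header row
#' of feature ids, first column of sample ids.
#'
#' @param table a [feature_table].
#' @param path output file path.
#' @param id_column name for the first (sample id) column.
#' @return the path, invisibly.
#' @export
write_feature_table <- function(table, path, id_column = "sample_id") {
  df <- as.data.frame(table$values, check.names = FALSE)
  out <- cbind(stats::setNames(data.frame(table$sample_ids,
                                          stringsAsFactors = FALSE), id_column), df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pair taxa and metabolite tables on shared samples
#'
#' Restricts both tables to the intersection of their sample ids, placed in a
#' deterministic lexicographic order. Matching is exact string equality; no
#' fuzzy matching is attempted, so mislabeled samples surface as drops rather
#' than silent mispairings.
#'
#' @param taxa,metabolites [feature_table] objects.
#' @return a `paired_dataset`: list with elements `taxa`, `metabolites`
#'   (row-aligned feature tables), `n_dropped_taxa`, `n_dropped_metabolites`.
#' @export
align_paired_samples <- function(taxa, metabolites) {
  stopifnot(inherits(taxa, "feature_table"), inherits(metabolites, "feature_table"))
  shared <- sort(intersect(taxa$sample_ids, metabolites$sample_ids))
  if (length(shared) == 0)
    stop("no shared sample ids between the taxa and metabolite tables")
  sub <- function(ft) feature_table(ft$values[shared, , drop = FALSE],
                                    feature_meta = ft$feature_meta,
                                    allow_negative = TRUE)
  structure(list(taxa = sub(taxa), metabolites = sub(metabolites),
                 n_dropped_taxa = length(taxa$sample_ids) - length(shared),
                 n_dropped_metabolites =
                   length(metabolites$sample_ids) - length(shared)),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf(paste0("paired_dataset: %d shared samples ",
                     "(%d taxa-only, %d metabolite-only dropped); ",
                     "%d taxa, %d metabolites\n"),
              length(x$taxa$sample_ids), x$n_dropped_taxa,
              x$n_dropped_metabolites, length(x$taxa$feature_ids),
              length(x$metabolites$feature_ids)))
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline with its default. Thresholds are
#' fractions in [0, 1]; counts are positive integers.
#'
#' @param prevalence_threshold minimum fraction of samples in which an ASV must
#'   be present (value > 0) to be retained; retention is inclusive at the
#'   threshold. Default 0.10.
#' @param mean_abundance_threshold genera with mean relative proportion
#'   strictly below this are dropped. Default 5e-5 (0.005%).
#' @param pseudocount added to every retained cell before proportions.
#' @param gunifrac_alpha abundance-weighting exponent of generalized UniFrac.
#' @param n_perm_procrustes Procrustes permutation count.
#' @param n_axes_procrustes ordination axes compared by Procrustes.
#' @param scca_n_perm_tune,scca_n_boot,scca_n_perm sparse-CCA tuning
#'   permutations, bootstrap resamples and test permutations.
#' @param fdr Benjamini-Hochberg significance cutoff for Spearman screening.
#' @param cv_repeats,cv_outer_folds,cv_inner_folds nested cross-validation plan.
#' @param sim_snr,sim_p_zero,sim_n_datasets,sim_beta0,sim_n_null simulation
#'   grid: signal-to-noise ratios, zero-coefficient probabilities, datasets per
#'   cell, intercept, null-arm permutations.
#' @param seed root random seed.
#' @return a named list of class `analysis_config`.
#' @export
analysis_config <- function(prevalence_threshold = 0.10,
                            mean_abundance_threshold = 5e-5,
                            pseudocount = 1,
                            gunifrac_alpha = 0.5,
                            n_perm_procrustes = 999L,
                            n_axes_procrustes = 2L,
                            scca_n_perm_tune = 50L,
                            scca_n_boot = 5000L,
                            scca_n_perm = 1000L,
                            fdr = 0.05,
                            cv_repeats = 100L,
                            cv_outer_folds = 5L,
                            cv_inner_folds = 5L,
                            sim_snr = c(0.5, 0.7, 3, 5),
                            sim_p_zero = c(0.05, 0.1, 0.5, 0.95),
                            sim_n_datasets = 100L,
                            sim_beta0 = 6 / sqrt(10),
                            sim_n_null = 500L,
                            seed = 1L) {
  cfg <- list(prevalence_threshold = prevalence_threshold,
              mean_abundance_threshold = mean_abundance_threshold,
              pseudocount = pseudocount,
              gunifrac_alpha = gunifrac_alpha,
              n_perm_procrustes = as.integer(n_perm_procrustes),
              n_axes_procrustes = as.integer(n_axes_procrustes),
              scca_n_perm_tune = as.integer(scca_n_perm_tune),
              scca_n_boot = as.integer(scca_n_boot),
              scca_n_perm = as.integer(scca_n_perm),
              fdr = fdr,
              cv_repeats = as.integer(cv_repeats),
              cv_outer_folds = as.integer(cv_outer_folds),
              cv_inner_folds = as.integer(cv_inner_folds),
              sim_snr = sim_snr, sim_p_zero = sim_p_zero,
              sim_n_datasets = as.integer(sim_n_datasets),
              sim_beta0 = sim_beta0, sim_n_null = as.integer(sim_n_null),
              seed = as.integer(seed))
  for (nm in c("prevalence_threshold", "mean_abundance_threshold", "fdr"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  for (nm in c("n_perm_procrustes", "scca_n_boot", "scca_n_perm",
               "cv_repeats", "cv_outer_folds", "cv_inner_folds"))
    if (cfg[[nm]] < 1) stop(nm, " must be a positive integer")
  if (any(cfg$sim_p_zero < 0 | cfg$sim_p_zero > 1)) stop("sim_p_zero must lie in [0, 1]")
  if (any(cfg$sim_snr <= 0)) stop("sim_snr must be positive")
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; omitted keys fall back to [analysis_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}
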