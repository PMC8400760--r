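# micrometab

Integrative analysis of paired microbiome–metabolome studies: does the
taxonomic composition of a microbial community agree with, covary with, and
predict the metabolite profile measured on the same samples?

The package is aimed at analysts of cohort studies with 16S amplicon
sequencing and (targeted or untargeted) NMR/MS metabolomics on shared
samples. It provides the full pipeline as tested, seeded, reusable
functions, plus a simulation framework so every stage can be validated
without any cohort data.

## What it computes

**Preprocessing.** ASV prevalence filtering (≥ 10% of samples, inclusive),
pseudocount, genus aggregation, closure to proportions, a 0.005%
mean-abundance filter with re-closure, and the centered log-ratio transform
`clr(x)_j = log x_j − mean_k log x_k`; metabolites are stabilized with
`log(x+1)` or the arcsine square root, both exactly invertible.

**Concordance.** Generalized UniFrac on a rooted phylogeny,

    d = Σ_b ℓ_b (p_b+q_b)^α |p_b−q_b|/(p_b+q_b)  /  Σ_b ℓ_b (p_b+q_b)^α ,

principal coordinates analysis by eigendecomposition of the doubly centered
squared-distance matrix, and the symmetric Procrustes test on the leading
axes: `m² = 1 − (Σσ_i)²`, `t = √(1−m²)`, with permutation p-values
`(1 + #{t_perm ≥ t_obs})/(n_perm + 1)`.

**Association.** Pairwise Spearman screening with joint Benjamini–Hochberg
control, and sparse canonical correlation by rank-1 penalized matrix
decomposition of the cross-product (soft-thresholded alternating updates
under `‖u‖₂ ≤ 1`, `‖u‖₁ ≤ c_u`), with permutation tuning of the penalty, a
paired-row bootstrap confidence interval, and a richness-preserving
permutation test (values shuffled within samples, preserving per-sample
richness and totals).

**Predictability.** A per-metabolite benchmark of random forest, RBF-kernel
support vector regression, elastic net, and sparse partial least squares
under repeated nested cross-validation, scored on the back-transformed
scale by predictive R² (`1 − PRESS/TSS`, fold-mean baseline = 0, negative
allowed) and Spearman correlation; a Bayesian hierarchical model
`stat ~ model + (1|repeat) + (1|repeat:fold)` summarizing fold-level
statistics into per-model posterior means and 95% credible intervals;
credible-interval predictability calls; and Borda rank aggregation (4/3/2/1
points per metabolite) across metabolites.

**Simulation.** Sparse log-normal community tables, linear metabolite
outcomes `Y = β₀ + Xβ + ε` with coefficients zeroed at probability
`p_zero` and noise scaled to an exact signal-to-noise ratio
(`σ_ε = sd(β₀+Xβ)/SNR`, `β₀ = 6/√10`), richness-shuffle null arms, and
random phylogenies.

## Worked example

Fully synthetic, so it runs anywhere: build a genus table, couple five
metabolites to it linearly at SNR 2, then ask the three questions.

```r
library(micrometab)

taxa   <- generate_community(n_samples = 60, n_taxa = 40, sparsity = 0.3, seed = 1)
counts <- feature_table(round(taxa$values * 1e4))          # count-like table
taxonomy <- setNames(paste0("genus", rep(1:10, 4)), counts$feature_ids)

genus <- filter_and_aggregate_taxa(counts, taxonomy)
#> feature_table: 60 samples x 10 features
clr <- clr_transform(genus)

sims <- sapply(1:5, function(j)
  simulate_linear_metabolite(clr, p_zero = 0.5, snr = 2, seed = j)$Y)
dimnames(sims) <- list(rownames(clr), paste0("met", 1:5))

# 1. concordance: do the two layers order samples similarly?
pro <- procrustes_test(pcoa(euclidean_distance(clr), k = 2),
                       pcoa(euclidean_distance(sims), k = 2),
                       n_perm = 999, seed = 1)
pro
#> Procrustes: m2 = 0.6096, t = 0.6248, p = 0.001 (999 permutations)

# 2. association: which groups drive it?
scca_inference(clr, sims, c_u = 2, c_v = 1.5,
               n_boot = 500, n_perm = 500, seed = 1)
#> sparse CCA: rho_1 = 0.9321; |support| = 8 taxa, 3 metabolites
#>   bootstrap 95% CI [0.8658, 0.9598]; permutation p = 0.001996
spearman_association_matrix(clr, sims, fdr = 0.05)
#> association_matrix: 10 x 5 pairs, 14 significant at q < 0.05

# 3. predictability: can taxa predict a single metabolite?
rec <- nested_cv_evaluate(clr, sims[, "met1"], models = c("rf", "enet"),
                          plan = cv_plan(n_repeats = 2, n_outer_folds = 5,
                                         n_inner_folds = 5, seed = 1),
                          metabolite_id = "met1")
aggregate(cbind(r2, scc) ~ model, rec, mean)
#>   model        r2       scc
#> 1  enet 0.6448405 0.7524476
#> 2    rf 0.3704721 0.6657343
```

Reading the numbers: the Procrustes `t = 0.62` with `p = 0.001` says the
taxon and metabolite ordinations agree far beyond permutation chance (the
smallest p reportable at 999 permutations). The sparse CCA finds a first
canonical pair correlating at 0.93, carried by 8 taxa and 3 metabolites,
with a bootstrap interval well away from zero and a richness-null
permutation p ≈ 0.002. In the benchmark the elastic net's mean held-out
predictive R² of 0.64 means it explains 64% of held-out variance relative
to the fold-mean baseline — consistent with data simulated at SNR 2, where
the attainable R² is `1 − 1/(1+SNR²) = 0.8`.

A command-line wrapper over the same functions ships at
`inst/cli/micrometab.R` with subcommands `preprocess`, `concordance`,
`spearman`, `scca`, `predict`, `rank`, `simulate`, writing seeded,
byte-reproducible TSVs.

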