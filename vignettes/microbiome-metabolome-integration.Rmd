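---
title: "Integrating paired microbiome and metabolome profiles: concordance, association, and predictability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating paired microbiome and metabolome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micrometab)
```

## The analysis problem

Stool samples profiled by 16S rRNA amplicon sequencing and NMR metabolomics
yield two tables over the same samples: a sparse, compositional table of
amplicon sequence variant (ASV) counts, and a table of metabolite
concentrations (targeted assays) or spectral-bin relative intensities
(untargeted assays). Three questions recur in cohort studies that collect
both:

1. **Concordance** — do the two data layers order samples similarly?
2. **Association** — which taxon/metabolite groups covary, marginally and
   multivariately?
3. **Predictability** — can taxonomic composition predict individual
   metabolite levels at all, and which learner does it best?

`micrometab` implements this pipeline end to end, together with a simulation
framework that generates data with known taxa-to-metabolite coupling so every
stage can be validated without access to any cohort.

## Preprocessing and transformations

The taxon pipeline applies, in order: a prevalence filter (ASVs present in at
least 10% of samples are retained — inclusive at the threshold), a
pseudocount of 1 added to every remaining cell, aggregation of ASVs to genus,
closure of each sample to relative proportions, and removal of genera with
mean proportion strictly below 0.005%. Two points are deliberate:

* Prevalence is computed on the raw counts (`> 0`) *before* the pseudocount;
  afterwards every feature would be 100% prevalent.
* After the mean-abundance filter the rows are re-normalized to sum to one.
  The composition must remain closed for the centered log-ratio transform
  (CLR) to retain its interpretation; without re-closure the removed mass
  would silently distort the geometric mean.

ASVs with no genus assignment are pooled into a sentinel `"unclassified"`
genus rather than dropped, conserving reads.

The CLR, `clr(x)_j = log x_j - mean_k log x_k`, maps each composition to a
zero-sum vector and is invariant to per-sample scaling, which removes the
unit-sum constraint before Euclidean geometry or regression is applied.
Metabolites are variance-stabilized with `log(x + 1)` (targeted
concentrations, non-negative, unbounded) or the arcsine square root
(untargeted relative intensities in [0, 1]). Both transforms are exact
bijections on their domains; the prediction benchmark inverts them so that
accuracy is always scored on the original concentration scale.

## Concordance: gUniFrac, PCoA, Procrustes

Generalized UniFrac with exponent `alpha` compares two relative-abundance
profiles along a rooted phylogeny:

$$d = \frac{\sum_b \ell_b\,(p_b+q_b)^\alpha\,\frac{|p_b-q_b|}{p_b+q_b}}
           {\sum_b \ell_b\,(p_b+q_b)^\alpha},$$

where the sum runs over branches, `ℓ_b` is branch length and `p_b`, `q_b`
are the descendant-leaf proportion totals in the two samples; branches
carrying no mass in either sample are skipped. `alpha = 0.5` (the default)
moderates the dominance of abundant lineages; `alpha = 1` is weighted
UniFrac, which the test suite verifies against an independently coded
brute-force branch walk. Distances are computed on the *unfiltered*
ASV-level table normalized to proportions, because the tree's leaves are
ASVs and filtering/aggregation would orphan them.

Ordination is classical principal coordinates analysis: eigendecomposition
of `B = -1/2 J (D ∘ D) J`. Negative eigenvalues (possible for non-Euclidean
dissimilarities) are reported but carry no coordinates; no Cailliez or
Lingoes correction is applied, keeping the eigenvalue spectrum honest.

Concordance is tested with the symmetric Procrustes statistic on the first
two axes: both configurations are centered and scaled to unit total sum of
squares, the optimal rotation comes from the SVD of the cross-product, and
`m² = 1 - (Σσ_i)²`, `t = sqrt(1 - m²)`. Significance uses 999 row
permutations of one configuration by default, with the add-one estimator
`p = (1 + #{t_perm ≥ t_obs}) / (n_perm + 1)`, which can never return an
impossible zero. The permutation stream is seeded separately so reruns are
bit-identical.

## Association: Spearman screening and sparse CCA

Marginal screening computes Spearman's rho for every (taxon, metabolite)
pair — on the CLR genus matrix and the transformed metabolite matrix; rank
correlation is invariant to the monotone per-metabolite transforms — with
two-sided p-values from the t approximation and Benjamini–Hochberg
adjustment over all pairs jointly (cutoff q < 0.05). Pairs involving a
constant column are recorded as missing and excluded from the BH family
rather than polluting it.

The multivariate view is a rank-1 penalized matrix decomposition of the
cross-product of the column-standardized matrices: maximize `u'X'Zv` subject
to `‖u‖₂ ≤ 1, ‖v‖₂ ≤ 1, ‖u‖₁ ≤ c_u, ‖v‖₁ ≤ c_v`. Column standardization is
adopted (and exposed) so the cross-product is a correlation-like matrix.
Updates alternate soft-thresholded, renormalized matrix-vector products;
the threshold at which an L1 constraint binds is found *exactly* by solving
a per-segment quadratic on the sorted absolute entries rather than by
bisection, which makes the constraint satisfaction machine-precision and
the permutation loops fast. Initialization is the leading singular pair of
the cross-product (deterministic); iteration stops at an update change
below 1e-6 or 200 sweeps. Because the L2 constraint replaces the classical
unit-variate-variance constraint, the reported `rho_1` (the Pearson
correlation of the two variates) only coincides with classical CCA when the
within-block correlation is the identity — the test suite checks exactly
that regime against the generalized-eigenproblem solution.

Penalty tuning sweeps one shared budget `c_u = c_v` over 10 points spanning
the feasible range `[1, sqrt(min(p, q))]`, scoring each by the standardized
gap between the observed Fisher-z of `rho_1` and its distribution over 50
row-permuted copies of the metabolite table; ties prefer the sparser
penalty. Inference combines a paired-row bootstrap percentile 95% interval
(default 5000 resamples; degenerate resamples with a constant column are
redrawn, capped at 10%) with a permutation test (default 1000) whose null
preserves community structure: the *richness shuffle* permutes each
sample's values across taxa, keeping per-sample richness, totals and value
multisets, and is applied to the taxa side only, leaving the metabolites
fixed.

## Predictability: four learners under nested cross-validation

Each metabolite is predicted from the CLR genus matrix by four learners with
fixed search grids: random forest (500 trees, `floor(sqrt(p))` candidate
features per split, no tuning), RBF-kernel support vector regression
(`C ∈ 2^{-5..15}` by powers of 4 — 11 values — crossed with
`γ ∈ 2^{-15..3}` — 10 values), elastic net (mixing between LASSO and ridge
in steps of 0.1; per mixing value a 100-point geometric lambda path from the
training-fold `λ_max` down four orders of magnitude), and sparse partial
least squares (components `K ∈ 1..10`, threshold `η ∈ 0.1..0.9`, concavity
fixed at 0.5), implemented here from its published soft-thresholded
direction-vector algorithm. The elastic-net `mixing` parameter is defined
explicitly as the weight on the L2 term; because the full grid is swept,
this convention fits the same model set as the reverse one.

The evaluation design is repeated nested cross-validation: by default 100
repeats of 5 outer folds, hyperparameters chosen inside each training
portion by 5-fold cross-validation maximizing mean R² on the transformed
scale (ties break to the earlier grid point), the winner refit on the full
training portion and scored on the held-out fold. Five outer folds are the
default with the fold count configurable, since both 5- and 10-fold variants
of this design are in circulation. Two fold-level statistics are recorded on
the *back-transformed* scale:

* **Predictive R²** `= 1 - PRESS/TSS`, with TSS taken about the held-out
  fold's own mean — so the naive fold-mean predictor scores exactly 0,
  and worse-than-baseline predictions go negative (they are not clipped);
* **SCC**, the Spearman correlation of truth and prediction.

Every (repeat, fold, model) cell derives its own seed substream from the
plan seed, so the full record table is bit-reproducible and independent of
execution order or thread count (computation is single-threaded).

## Performance inference: hierarchical model and Borda scores

Fold-level statistics are correlated within repeats and folds, so model
comparison uses a Gaussian hierarchical model per metabolite and metric:

$$stat_{m,r,f} = \mu + \beta_m + a_r + b_{r,f} + \varepsilon,\qquad
a_r \sim N(0, \sigma^2_{repeat}),\; b_{r,f} \sim N(0, \sigma^2_{fold}),$$

with weakly informative priors — Normal(0, sd 10) on `μ` and the model
effects, Exponential(1) on the three scales — sampled by MCMC (4 chains,
1000 warmup + 1000 kept draws each; the Gelman–Rubin statistic is reported
and warned about above 1.01). On a balanced design the per-model posterior
means agree with the generalized-least-squares estimate (the cell means) up
to Monte-Carlo error, which the test suite checks.

A metabolite is called *predictable* when its best model's 95% credible
interval excludes zero from below (`ci_above_zero`), or under the stricter
`scc_above_0.3` rule for the Spearman metric. Judging the best model
encodes an existence claim: some model beats the null. Models are ranked
across metabolites by Borda count — 4/3/2/1 points by posterior-mean rank,
exact ties sharing the mean of the contested points so every metabolite
contributes exactly 10 points.

## The simulation framework

The generator emulates the features of real paired data that drive the
pipeline's behavior:

* **Community tables**: log-normal abundances (meanlog 0, sdlog 1) masked
  to a target zero fraction (default 0.3, a typical genus-table sparsity)
  and closed to proportions; or row bootstraps of a supplied table.
* **Linear coupling**: `Y = β₀ + Xβ + ε` with `β_j` zero with probability
  `p_zero` (grid 0.05, 0.1, 0.5, 0.95) and otherwise standard normal,
  `β₀ = 6/√10`, and `σ_ε = sd(β₀ + Xβ)/SNR` (sample standard deviation,
  n−1 denominator) at SNR 0.5, 0.7, 3, 5 — so the realized signal-to-noise
  ratio is exact by construction. X enters on the CLR scale; generated
  communities receive a count-like pseudocount (depth 10⁴, +1) before
  closure and CLR, mirroring the preprocessing treatment of zeros. If every
  coefficient is zeroed the noise scale is undefined and falls back to 1
  with a warning and a flag.
* **Null arm**: a reference outcome is fixed and the community is
  richness-shuffled before each evaluation, decoupling X from Y while
  preserving per-sample structure. 500 permutations is the default, with
  1000 also exposed.
* **Random phylogenies**: random binary topologies with Exponential(1)
  branch lengths, midpoint rooted — fixtures for the distance tests.

Each positive-arm dataset is split 80/20, hyperparameters tuned by 10-fold
cross-validation on the training 80%, and scored on the held-out 20%.
Along the SNR axis the community bootstrap, coefficient draw and
standardized noise draws are shared (common random numbers) with only the
noise scale changing, so SNR contrasts are paired and the monotone
signal-strength response is estimated without between-dataset noise.

**What passing tests do and do not show.** The generator produces linear,
homoscedastic coupling on CLR scale with independent log-normal taxa. Real
data add phylogenetic correlation among taxa, zero inflation beyond
Bernoulli masking, heteroscedastic and nonlinear taxa–metabolite
relationships, batch structure, and measurement error in both layers.
Calibration and recovery results here therefore validate the
*implementation* (correct statistics, correct null distributions, correct
bookkeeping), not the biological adequacy of any model on cohort data.

## Numerical choices and degenerate inputs

* Missing cells in input tables are an error, never imputed; sample pairing
  is exact string matching with a deterministic lexicographic shared order.
* Newick trees that parse as unrooted (basal multifurcation) are midpoint
  rooted by default; already-rooted binary trees are left untouched, with
  `midpoint = "always"/"never"` overrides. A two-leaf basal split is
  treated as rooted under the default policy.
* All permutation p-values use the add-one estimator.
* Constant columns abort standardization with a named error rather than
  propagating NaN; constant training outcomes short-circuit every learner
  to the constant prediction; constant held-out truth records R² as
  missing.
* All randomness flows from one root seed through named Lehmer-mixed
  substreams (per dataset, permutation, repeat, fold, model), each below
  2³¹, so any single unit of work is independently reproducible.

## Problem sizes used by the test suite

The suite validates oracle agreement on 50 random 8-leaf tree instances and
20 whitened 100×3×3 CCA instances; calibrates the Procrustes and sparse-CCA
permutation tests on 500 null datasets each at 199 permutations; and runs
the simulation study on a 2×2 grid (SNR 0.5/5 × sparsity 0.5/0.95) with 20
datasets per cell, 100 samples × 30 taxa, all four learners, plus a
20-permutation null arm. These sizes were chosen to estimate each property
with useful precision while keeping a full run on one CPU comfortable.

## Known limitations

Only the first canonical variate pair is fit; multi-factor or supervised
CCA variants are out of scope, as are classification tasks,
feature-importance extraction, unweighted UniFrac, Mantel tests, and
BIOM-HDF5 binary parsing. The hierarchical performance model applies no
multiplicity adjustment across metabolites for predictability calls, and
uses an identity link on R²/SCC taken literally, so posterior intervals can
extend beyond the metrics' natural ranges for extreme inputs.
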