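Package: micrometab
Title: Integrative Microbiome-Metabolome Concordance, Association and
    Predictability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for paired microbiome-metabolome studies:
    compositional preprocessing of amplicon sequence variant tables
    (prevalence filtering, pseudocounts, genus aggregation, centered
    log-ratio transformation), ordination-based concordance testing
    (generalized UniFrac, principal coordinates analysis, symmetric
    Procrustes permutation test), pairwise Spearman screening with
    Benjamini-Hochberg control, sparse canonical correlation by rank-1
    penalized matrix decomposition with permutation tuning, bootstrap
    confidence intervals and a richness-preserving permutation test, a
    per-metabolite machine-learning predictability benchmark (random
    forest, radial-kernel support vector regression, elastic net, sparse
    partial least squares) under repeated nested cross-validation with
    predictive R-squared and Spearman metrics on the back-transformed
    scale, Bayesian hierarchical modeling of fold-level performance with
    Borda rank aggregation, and a simulation framework with a sparse
    linear taxa-to-metabolite generative model at controlled
    signal-to-noise ratios plus richness-permutation nulls.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    glmnet,
    e1071,
    randomForest,
    rjags,
    coda,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
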