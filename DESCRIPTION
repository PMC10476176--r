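Package: longevitr
Title: Phylogenetic Comparative Transcriptomics of Mammalian Longevity
Version: 0.1.0
Authors@R: person("Maintainer", "Anonymous", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for cross-species analysis of gene expression
    and longevity. Provides TMM-RPKM log normalization and filtering of
    orthologous count matrices, the Tau species-specificity index,
    phylogeny-aware imputation of life-history traits with an evaluation
    harness (NRMSE, slope bias, missingness-mechanism grid), per-gene
    phylogenetic regression of expression on longevity traits under OLS,
    Brownian-motion and Ornstein-Uhlenbeck residual models with a two-step
    robust P-value procedure and Westfall-Young maxT permutation adjustment,
    polygenic sum-statistic (SUMSTAT) gene-set enrichment with empirical
    nulls, and integration with externally computed selection-intensity (k)
    tables.  A synthetic-data generator with ground-truth labels supports
    calibration and recovery testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
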