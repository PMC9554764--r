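Package: hostassoc
Title: Host-Associate Population Genetic Structure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether host-plant population genetic structure
    predicts the population structure of intimately associated species
    (herbivores, parasites, mutualists) over and above geography and climate.
    Builds pairwise genetic (Weir-Hill multilocus FST from biallelic
    pseudolocus counts), geographic (great-circle), and climatic (PCA-space
    Euclidean) distance matrices; estimates Spearman correlations among them
    with bootstrap intervals; fits zero-inflated beta multiple matrix
    regressions with randomization (MMRR) significance; fits a Bayesian
    allele-frequency covariance model with isolating alpha terms by MCMC;
    and pools per-pair effects by random-effects (DerSimonian-Laird)
    meta-analysis with interaction-type subgroup tests and close-relative
    pruning scans. Includes a synthetic-data generator that plants known
    isolation-by-distance, isolation-by-climate, and isolation-by-host
    effects so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
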