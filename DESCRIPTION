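Package: sembayes
Title: Structural Equation Model Bayesian Variable Selection for Multi-Trait GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-trait Bayesian variable-selection regression (multi-trait
    BayesC-pi) extended with a recursive structural equation model among
    phenotypes (SEM-BayesC-pi). Provides Gibbs samplers with mixture priors
    over all trait-combination inclusion indicators, discovery of the
    phenotypic causal structure from posterior residual covariances
    (partial correlations, highest-posterior-density decision rule, and the
    Inductive Causation algorithm), decomposition of marker effects into
    direct, indirect and overall components, genomic-window association
    inference via the window posterior probability of association (WPPA),
    a simulator for two-trait causal genetic architectures, and a partial
    area-under-the-ROC (pAUC5) benchmarking harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
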