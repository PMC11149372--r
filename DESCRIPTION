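Package: equigen
Title: Equitable Multi-Ancestry Clinico-Genomic Disease Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and evaluation toolkit for studying machine-learning
    performance disparities across ancestry groups in case-control disease
    prediction. Generates multi-ancestry genotype/phenotype cohorts under a
    liability-threshold model with built-in data inequality and cross-ancestry
    effect-size shift, applies standard genotype quality control (minor allele
    frequency, missingness, Hardy-Weinberg exact test, windowed LD pruning,
    ANOVA-F feature selection), fits L2-regularized logistic regression and a
    single-hidden-layer neural network, runs mixture, independent, naive-transfer
    and transfer-learning experiment schemes over replicate runs, and summarizes
    disparity gaps and transfer-learning improvements with threshold-free and
    prevalence-adjusted performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
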