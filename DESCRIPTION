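Package: rarank
Title: Rank Aggregation with Re-Balance for Feature Screening in
    Class-Imbalanced Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Feature screening for two-class, class-imbalanced feature tables
    such as metabolomics or proteomics intensity matrices. Ranks features with
    eight filter statistics (Welch t, Fisher score, Hellinger distance, Relief,
    ReliefF, information gain, Gini index, R-value), fuses the rankings into a
    consensus list by cross-entropy Monte Carlo minimisation of the Spearman
    footrule distance, and couples the aggregation with seven re-balancing
    regimes (random over/under-sampling, SMOTE, smoothed bootstrap). Includes
    imbalance-aware evaluation (Gmean, F1, AUCROC, AUCPRC, cross-validated
    top-k selection with a random forest), a two-class Gaussian simulator for
    ranking-concordance studies, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
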