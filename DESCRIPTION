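Package: hiprs
Title: High-Order Interaction-Aware Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds interpretable polygenic risk scores that model high-order
    SNP-SNP interactions. Candidate allele patterns are mined from the case
    class by frequent-itemset search above a support threshold, ranked by
    empirical mutual information with the outcome, filtered by a greedy
    minimum-redundancy/maximum-relevance selection, and weighted by an
    unpenalized logistic regression. Includes an epistatic phenotype
    simulator with label-flipping noise and class-imbalance undersampling,
    bootstrap resampling from empirical genotype-by-class tables, additive
    penalized baselines, imbalance-aware evaluation metrics (trapezoidal AUC,
    rectangular-rule average precision), a cross-validated hyperparameter
    grid search, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
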