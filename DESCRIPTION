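Package: subtypecurves
Title: Learning Curves for RNA-Seq Based Breast Cancer Molecular Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates how breast-cancer molecular subtype and receptor-status
    prediction accuracy depends on training-set size and RNA-seq read depth.
    Provides a negative-binomial synthetic-cohort generator emulating the five
    intrinsic subtypes with realistic class imbalance, median-of-ratios
    normalization and variance/panel feature selection, a nearest shrunken
    centroids classifier implemented from the published formulas alongside
    penalized multinomial regression and random forests, a nested stratified
    cross-validation learning-curve engine with binomial read-count thinning,
    single-gene logistic receptor-status models with ROC/Youden cutoffs, and an
    unsupervised arm (correlation-distance average-linkage clustering with
    significance-of-clustering pruning and priority-ordered subtype label
    transfer). Results are tidy tibbles with broom-style tidiers and ggplot2
    autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ape,
    DESeq2,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
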