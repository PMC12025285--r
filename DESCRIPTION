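Package: hyperfuse
Title: Longitudinal Multimodal Feature Selection with Hypergraph
    Regularization and Multi-Kernel Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sparse multi-task feature selection for longitudinal multimodal
    cohorts (e.g. region-of-interest summaries from serial neuroimaging).
    Feature selection at each visit is one task; an l2,1 group penalty ties
    tasks together so the same features are selected across visits, a fused
    lasso penalty enforces temporal smoothness of the coefficient profiles,
    and a KNN-hypergraph Laplacian penalty preserves higher-order similarity
    structure among subjects. The composite objective is minimised by a
    monotone accelerated proximal gradient method with backtracking line
    search and an exact two-stage proximal operator. Selected features from
    each modality are fused through a convex combination of linear kernels
    and classified with a support vector machine on the precomputed mixed
    Gram matrix. Includes a synthetic longitudinal cohort generator with
    planted effects, stratified cross-validated evaluation with ROC/AUC and
    feature-stability reporting, ablation and hyperparameter-sweep runners,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
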