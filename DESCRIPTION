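Package: toastnet
Title: Causal Convolutional Networks with Active Model Adaptation for
    TOAST Stroke Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Interpretable classification of ischemic-stroke TOAST
    subtypes (LAA, CE, SAO, OC, UND) from tabular clinical cohorts.
    Features are ranked by gradient-boosted-tree importance and fed, most
    important first, to a one-dimensional causally padded convolutional
    network in four architectural variants.  Training uses a focal loss
    regularized by a Kullback-Leibler divergence term, and a pool-based
    active-learning cycle (train, query, append, fine-tune) that scores
    samples by entropy, top-2 margin, or a mixed uncertainty criterion.
    Includes a synthetic cohort generator emulating the class imbalance,
    mixed feature types and sparse missingness of real stroke registries,
    mode imputation, stratified cross-validation, and weighted multiclass
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    xgboost,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
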