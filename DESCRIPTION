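Package: qsarboost
Title: QSAR Modelling of KRAS G12C Inhibition with Gradient-Boosted Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative structure-activity relationship (QSAR) pipeline
    for identifying covalent KRAS G12C inhibitors among approved drugs.
    Curates IC50 activity tables into a modelling-ready dataset, builds
    conjoint molecular-fingerprint feature matrices, trains second-order
    gradient-boosted regression-tree models (classification and pIC50
    regression) with an exact greedy split finder implemented from the
    boosting objective, validates them by k-fold cross-validation, external
    testing, Y-randomization and a standardized-residual applicability
    domain, explains predictions with exact Shapley values, and screens
    candidate covalent-drug libraries for predicted inhibitors. Includes a
    synthetic-data generator that emulates the statistical structure of the
    KRAS G12C activity dataset so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
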