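Package: qsprblend
Title: Interpretable Blending Ensembles for QSPR Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines four decision-tree ensemble learners (random forest,
    extremely randomized trees, adaptive boosting, gradient boosting) through
    uniform, linear and non-linear ("any") level-1 blenders for quantitative
    structure-property relationship (QSPR) regression and binary
    classification on molecular-descriptor tables. Aggregates impurity-based
    feature importances across the base learners by a weighted-sum rule to
    give a single interpretable feature ranking, and provides the matching
    evaluation suite (RMSE, R-squared, accuracy, precision, recall, F1,
    Matthews correlation coefficient) together with a synthetic descriptor
    generator with planted informative features for benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    ranger,
    rpart,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
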