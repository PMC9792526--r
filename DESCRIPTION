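Package: strokeqi
Title: Quadratic-Interaction Deep Models and Multi-Objective Learning for
    Stroke Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for four-state stroke risk modeling on mixed
    categorical/continuous screening data. Implements a base multilayer
    perceptron, a quadratic-interaction deep model (QIDeep) whose order-2
    feature pairs are screened by Shapley interaction values, and a
    two-objective multi-gate mixture-of-experts model (MMOE) that jointly
    predicts a four-level risk state and binary stroke occurrence.
    Includes exact and permutation-sampled Shapley attribution with
    force-plot and dependence-plot data export, per-class evaluation
    metrics with run aggregation, and a synthetic-data generator with
    planted pairwise interaction effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nnet,
    optparse,
    randomForest,
    readr,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
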