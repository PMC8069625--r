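Package: wearday
Title: Classification of Human Wear and Delivery Days in Accelerometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cleaning activity-count accelerometry studies in which
    devices are mailed to participants and record postal transit alongside
    human wear. Provides midnight-aligned day segmentation with zero-padding,
    minimal and full processing filters, extraction of eight vector-magnitude
    features (mean, variance, maximum, 95th quantile, absolute energy,
    absolute change, kurtosis, skewness), seven supervised day classifiers
    (random forest, restricted-cubic-spline logistic regression, mixed-effects
    logistic regression, multilayer perceptron, and convolutional, recurrent
    and convolutional-recurrent networks on the raw 1440-by-3 count arrays),
    participant-grouped Monte Carlo cross-validation with sensitivity, positive
    predictive value, F1 and Brier scoring, and a synthetic generator of
    delivery-adulterated assessments for testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    randomForest,
    lme4,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
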