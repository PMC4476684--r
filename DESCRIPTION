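Package: decisionpath
Title: Personalized Decision-Path Models for Clinical Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lazy, per-patient decision-path classifiers for discrete tabular
    biomedical data. For each test individual a single conjunctive path of
    features observed in that individual is grown greedily over the training
    data using one of three split criteria -- a two-sample Bayesian
    (Dirichlet-multinomial) score, information gain, or a leave-one-out AUC
    criterion -- then pruned bottom-up at the best-scoring step, and converted
    into a BDeu-smoothed probability of the outcome. Includes a population
    decision-tree comparator with smoothed leaves, MDL-based entropy
    discretization of continuous predictors, chi-square predictor screening,
    stratified k-fold cross-validation, and probabilistic evaluation via AUC,
    Brier score and Brier skill score, together with seeded synthetic-data
    generators for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
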