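Package: toxtiers
Title: Tiered Bayesian Prediction of Rat Acute Oral Toxicity Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic, tiered assessment of rat acute oral toxicity
    categories (the five ordered LD50 bands of EU CLP, extended with a
    low-concern Category 5) from chemical structure and surrogate data.
    Tier 0 converts Cramer structural classes into prevalence-scaled
    category-probability distributions; Tier 1 updates them with in
    silico LD50 predictions (external QSAR, an in-package random forest)
    and SMARTS structural alerts through a Bayesian proportional-odds
    logistic regression with Laplace coefficient priors; Tier 2 adds in
    vitro cytotoxicity (AC50) with censoring. Categories are attributed
    by an exclusionary rule that discards low-probability categories and
    selects the most hazardous survivor. Includes a calibrated synthetic
    compound-data generator, evaluation reports (confusion matrices,
    over/under-prediction accounting, LD50-variability category-switch
    analysis) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    ChemmineR,
    ChemmineOB,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    coda,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
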