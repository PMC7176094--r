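Package: psaml
Title: Propensity Score Adjustment for Volunteer Online Samples with
    Machine Learning Propensity Estimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects selection bias in volunteer (nonprobability) online
    samples by Propensity Score Adjustment (PSA). A reference probability
    sample and the volunteer sample are stacked, the probability of
    belonging to the volunteer sample is modelled from shared covariates
    with one of six class-probability estimators (logistic regression,
    decision trees, random forests, gradient boosting, k-nearest
    neighbours, naive Bayes), and the volunteer units are reweighted with
    either Horvitz-Thompson-type propensity-class weights or Hajek-type
    inverse-odds weights. Includes a fully specified simulator of a
    fictitious voter population with MCAR, MAR and NMAR selection
    mechanisms, a replicated Monte-Carlo engine reporting bias and mean
    squared error against the finite-population truth, and repeated
    k-fold cross-validated log-loss tuning of estimator hyperparameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    FNN,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
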