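Package: saeboost
Title: Unit-Level Small Area Estimation with Gradient Boosted Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unit-level small area estimation of prevalences and average
    ratings for nested geographic regions. A predictive model is trained on
    survey respondents using registry features, the unsurveyed population is
    predicted, and combined observed/predicted responses are aggregated to
    neighborhoods, districts and municipalities with model-agnostic bootstrap
    percentile prediction intervals that include a finite-sample correction.
    Includes a reference implementation of gradient boosted regression trees
    with missing-value default-direction splits, oblique geographic coordinate
    features, sequential random-forest imputation, a synthetic population
    generator for method evaluation, and an out-of-sample validation suite
    (Brier score, negative log-likelihood, AUC, ROC and calibration curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xgboost,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
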