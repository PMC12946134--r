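Package: cardiofs
Title: Feature Selection and Interpretable Classification for Cardiovascular Risk Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and benchmarking cardiovascular-disease risk
    classifiers on NHANES-style mixed-type cohort tables. Implements four
    feature-selection strategies (a Pearson/chi-squared redundancy filter,
    an alternating decision tree learner, cross-validated consensus selection
    over gradient-boosting importances, and a hypergraph cut-conductance
    feature scorer), a seeded synthetic cohort generator with planted
    class-informative features, cohort preparation (missingness filtering,
    complete-case reduction, random undersampling, stratified splitting,
    descriptive tables), classifier benchmarking with exact binomial
    confidence intervals, and Shapley-value attributions for fitted models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
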