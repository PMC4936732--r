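Package: tbirank
Title: Partial-AUC Importance Ranking and Bayesian Network Analysis for
    Traumatic Brain Injury Outcome Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ranking admission predictors of six-month outcome
    after traumatic brain injury by the drop in cross-validated ROC indices
    (full AUC and McClish-standardized partial AUC targeted at the 90-100%
    specificity or sensitivity range), for stepwise model simplification with
    a DeLong/bootstrap significance stopping rule, and for constrained
    discrete Bayesian-network analysis of predictor associations
    (hill-climbing structure search under a BIC score, exact inference by
    variable elimination).  Includes a calibrated synthetic cohort generator
    emulating the CRASH-trial admission variable schema, its marginal
    frequencies and its missing-data mechanisms, so the full analysis
    pipeline can be exercised and tested without the trial data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
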