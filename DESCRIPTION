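Package: eldshunt
Title: Drainage-Test Improvement Scoring and Shunt-Outcome Prediction in
    Normal Pressure Hydrocephalus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating continuous external lumbar drainage (ELD)
    as a prognostic test before shunt surgery in idiopathic normal pressure
    hydrocephalus (iNPH). Implements direction-aware z-score
    standardization of computerized cognitive tests, composite cognitive,
    gait, combined and traditional improvement rates, rule-based ELD and
    shunt responder classification, Firth penalized logistic regression
    (Jeffreys-prior bias reduction for small or separated samples) with
    Wald and profile penalized-likelihood intervals, ROC analysis with
    Youden-index cutoffs, DeLong tests, stratified bootstrap confidence
    intervals, permutation tests, calibration assessment (Spiegelhalter
    test, recalibration slope, binned calibration error), and a synthetic
    iNPH cohort generator for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
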