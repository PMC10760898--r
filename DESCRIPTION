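Package: chetools
Title: Catastrophic Health Expenditure Thresholds and Multilevel Determinant Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing catastrophic health expenditure (CHE) in
    household expenditure surveys with a two-stage cluster design. Implements
    data-driven region-specific CHE thresholds built from households that are
    pushed below the poverty line by out-of-pocket health spending, CHE
    classification under competing threshold policies (WHO 40% of nonfood
    expenditure, 10% of total expenditure, and the data-driven thresholds),
    a PCA-based asset wealth index with quintile classes, fixed-effects and
    random-intercept logistic regression fitted by adaptive Gauss-Hermite
    quadrature with intraclass correlation, likelihood-ratio tests,
    generalized variance inflation factors and ROC/AUC evaluation, plus a
    synthetic household-survey generator emulating a stratified two-stage
    cluster design for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
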