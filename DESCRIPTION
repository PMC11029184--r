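Package: rsindex
Title: Enhanced Risk Scoring for Patients Discharged from Intensive Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating a continuously updated risk
    score for ward patients recently discharged from an intensive care unit
    (ICU). A static risk of in-hospital death or ICU readmission is estimated
    at ICU discharge with an L1-regularised logistic model over summaries of
    the ICU stay; a dynamic score is obtained from a one-class kernel density
    model of vital-sign normality fitted to discharge-day observations; the
    two are fused by a time-decaying linear blend (the Risk Score Index).
    Includes table-driven implementations of four published Early Warning
    Score systems (MEWS, SEWS, NEWS, CEWS), an observation-level evaluation
    framework (time-window AUROC, grouped percentile bootstrap,
    Hosmer-Lemeshow, Brier and Cox calibration, trigger-burden curves), and a
    seeded synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    pROC,
    withr,
    yaml,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
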