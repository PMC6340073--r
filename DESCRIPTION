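Package: lipir
Title: Derivation and Evaluation of Compound Infection Risk Indices in
    Lupus Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to derive, apply and evaluate compound
    clinical-immunological infection risk scores in cohorts of systemic
    lupus erythematosus patients: longitudinal cohort data handling with
    median/IQR summaries and adjusted-mean disease activity, risk-ratio
    estimation from 2x2 tables and log-binomial / modified-Poisson /
    logistic regression with AIC model selection, ROC dichotomization
    cutoffs by the closest-to-corner criterion, integer point assignment
    by risk-ratio rank, patient scoring, and diagnostic performance
    evaluation (exact binomial confidence intervals, likelihood ratios,
    AUC with DeLong inference) on baseline and nested case-control
    datasets.  A synthetic-cohort generator with log-normal marginals
    fitted from published median/IQR summaries makes the full pipeline
    testable without patient-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    tools,
    jsonlite,
    sandwich,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
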