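Package: campusmh
Title: Forecasting On-Campus Mental Health Consultations from Campus
    Social Media Language
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying whether the language of a
    campus online community tracks on-campus mental health service
    utilization.  Per-outcome n-gram support vector classifiers flag
    symptomatic expressions of depression, anxiety, stress, suicidal
    ideation, and psychosis in timestamped posts; monthly expression
    prevalence is residualized (moving-window trend and seasonality
    removal with augmented Dickey-Fuller verification) and related to
    normalized consultation rates through lagged, controlled regression;
    seasonal ARIMA models with and without social-media covariates are
    compared under anchored cross-validation with permutation and
    dependent-overlapping-correlation tests; and high- versus
    low-consultation months are characterized with a sparse additive
    generative model (SAGE) and psycholinguistic lexicon profiling under
    false-discovery-rate control.  A synthetic-data module generates
    consultation series and coupled post streams so the full analysis is
    testable without access to confidential records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    jsonlite,
    Matrix,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
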