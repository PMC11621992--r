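Package: rfjem
Title: Job-Exposure Matrix Linkage and Conditional Logistic Analysis of
    Occupational RF-EMF Exposure in Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links a radiofrequency electromagnetic field (RF-EMF)
    job-exposure matrix keyed by 4-digit ISCO88 occupation codes to
    lifetime occupational histories of case-control study participants
    under three increasingly specific attribution methods, computes
    cumulative and time-weighted-average exposure over lags and time
    windows before a diagnosis/reference date, categorizes exposure by
    control-based percentile cut-points, and estimates odds ratios by
    stratified conditional logistic regression using the exact
    conditional likelihood. Includes a synthetic-data generator that
    emulates the structure of a multicentre occupational brain-tumour
    study so every pipeline stage is testable with known effect sizes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    survival,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
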