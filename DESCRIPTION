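Package: carematrix
Title: Adherence Scoring for Longitudinal Psychosocial Assessment Schedules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores per-patient psychosocial assessment histories in pediatric
    oncology on a five-level adherence matrix adapted from the Psychosocial
    Standards of Care (Standard 1.A), covering social work assessments (SWA)
    and provider biopsychosocial assessments (PBA). Resolves temporal
    eligibility windows (initial-contact windows, quarterly treatment bins,
    end-of-treatment and annual post-treatment anniversaries) over longitudinal
    event data with explicit censoring, summarizes and compares cohorts with
    pooled one-tailed t-tests and 95 percent confidence intervals, renders
    demographic tables, and generates synthetic cohorts with exact
    target-level adherence structure so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    lubridate,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
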