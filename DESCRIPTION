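Package: amytrial
Title: Amyloid-PET Quantification Metrics and Prevention-Trial Sample Sizes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing dynamic (reference Logan DVR) and static
    (SUVR) quantification of amyloid PET in the design of Alzheimer's disease
    prevention trials. Provides a synthetic longitudinal PIB-PET cohort
    generator with test-retest-calibrated measurement noise, simulation of
    simplified reference tissue model time-activity curves with SUVR and
    reference Logan DVR quantification, Centiloid-based burden stratification,
    linear mixed-effects estimation of annualized accumulation rates,
    test-retest variability statistics and accumulator classification,
    Bland-Altman and covariate association analyses, and a noncentral-t
    two-sample power engine that converts group accumulation summaries into
    per-arm sample sizes for enrichment scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
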