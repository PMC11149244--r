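Package: ckdlabscan
Title: Kidney Function Testing Patterns from Outpatient Laboratory Records
Version: 0.1.0
Authors@R:
    person("CKD", "Labscan Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for analysing chronic kidney disease (CKD) screening and
    monitoring patterns in large outpatient laboratory databases. Computes
    estimated glomerular filtration rate (eGFR) with the 2021 race-free
    CKD-EPI creatinine equation, converts urinary protein-to-creatinine
    ratios and semi-quantitative dipstick results into predicted
    albumin-to-creatinine ratios (pACR) via published crosswalk equations,
    assigns KDIGO G stages, albuminuria categories and risk classes, builds
    one index assessment per patient (creatinine/urinary pairing within a
    12-month window, laboratory-based diabetes flag, requesting-specialty
    attribution), and estimates stage-stratified cumulative incidence of
    repeat creatinine testing by the Kaplan-Meier product-limit method.
    Includes a seeded synthetic laboratory-record generator calibrated to
    published stage, pairing, albuminuria, specialty and retest
    distributions, so the full pipeline can be exercised and validated
    without access to proprietary source data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    survival,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
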