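Package: cdclaims
Title: Validation of Claims-Based Case-Identification Algorithms for Crohn's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating case-identification (phenotyping)
    algorithms for Crohn's disease in monthly health-insurance claims data.
    Implements month-level inclusion criteria combining confirmed ICD-10
    diagnosis codes with same-month prescription or surgical codes, age-stratified
    sampling of criterion-positive and criterion-negative patients with
    Horvitz-Thompson weights, two-reviewer chart-review adjudication, diagnostic
    validity statistics (sensitivity, specificity, PPV, NPV) with Clopper-Pearson
    exact confidence intervals, weighted extrapolation of the sampled contingency
    table to the source cohort, sample-size calculation for a proportion, and
    chance-corrected agreement coefficients (Cohen's kappa, weighted kappa,
    Gwet's AC1). A seeded generator of synthetic hospital-scale claims databases
    with known ground truth supports end-to-end testing of the whole design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
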