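Package: acsmetrics
Title: Facility-Level Antenatal Corticosteroid Coverage and Overtreatment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes facility-level balancing metrics for antenatal
    corticosteroid (ACS) administration from patient-level perinatal
    registry records (coverage before 34 weeks, optimally timed coverage,
    term exposure among recipients, overall administration rate), applies
    the exclusion cascade, minimum-volume and median-absolute-deviation
    outlier filters used in facility-level quality analyses, fits
    standardized multivariable linear models of the four metrics on
    facility characteristics with variance-inflation diagnostics, and
    projects the consequences of raising ACS coverage (benefits and
    overtreatment) with a scenario simulation engine.  A calibrated
    synthetic registry generator with planted facility-level structure
    makes every stage testable without access to real registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    car,
    withr
Config/testthat/edition: 3
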