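Package: endoval
Title: Validation of Administrative Claims Diagnoses Against Surgically
    Confirmed Endometriosis
Version: 0.1.0
Authors@R:
    person("UPDB", "Validation Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for validating endometriosis diagnoses (and the
    superficial, ovarian-endometrioma and deep-infiltrating subtypes)
    derived from ICD-coded administrative health data against a surgical
    reference standard recorded on rASRM operative forms. Builds 2x2
    contingency tables, computes percent agreement, AUCR, sensitivity,
    specificity, NPV, PPV and Cohen's kappa with percentile-bootstrap
    confidence intervals, and runs error and subgroup analyses. Includes
    a synthetic cohort generator so the whole pipeline is testable
    without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
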