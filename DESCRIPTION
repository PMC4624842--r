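Package: aqpa
Title: Antibiotic Prescribing Quality Indicators and Attitude-Effect Modelling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the twelve ESAC (European Surveillance of Antimicrobial
    Consumption) prescription-quality indicators per physician-year from
    ATC-coded dispensing records expressed in defined daily doses (DDD),
    classifies physicians against national reference values into the binary
    Appropriate Quality Prescription of Antibiotics (AQPA) outcome, and
    quantifies the effect of physicians' knowledge and attitudes on AQPA with
    longitudinal random-intercept logistic models summarised as interquartile
    odds ratios (IqOR).  Includes a synthetic-cohort simulator with known
    ground-truth attitude effects, test-retest ICC utilities for questionnaire
    item retention, and delimited-text readers/writers for every pipeline
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
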