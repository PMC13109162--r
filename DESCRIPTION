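Package: gews
Title: Validation Toolkit for Geriatric Early Warning Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating ward-based early warning scores on
    longitudinal vital-sign data, built around the Geriatric Early Warning
    Score (GEWS) and the National Early Warning Score (NEWS). Provides
    declarative band-table scoring of timestamped observation sets,
    hospitalization episode construction with event/non-event/neutralized
    labeling, two-stage missing-score imputation (zero rules plus last
    observation carried forward), discrimination metrics (AUROC, area under
    the precision-recall curve), alert-burden metrics (number-needed-to-
    evaluate, rate-of-alerts, alerted-outcome-event-rate per 100
    patient-days), patient-clustered bootstrap confidence intervals and
    paired Monte Carlo permutation tests, and a seedable synthetic
    geriatric-ward cohort generator so every pipeline stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
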