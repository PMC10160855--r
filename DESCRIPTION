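Package: vacalibrate
Title: Multi-Cause Calibration of Verbal Autopsy Cause-Specific Mortality
    Fractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates population cause-specific mortality fractions (CSMFs)
    from computer-coded verbal autopsy (CCVA) output while correcting for
    algorithm misclassification. Misclassification matrices are estimated by
    pseudo-maximum-likelihood compositional regression of multi-cause CCVA
    scores on multi-cause reference (MITS) cause assignments, and calibrated
    CSMFs are obtained by generalized-Bayes inference on the balance equation
    q = M'p with a Kullback-Leibler loss, for a single algorithm or an
    ensemble of algorithms. Includes WAIC comparison of calibrated versus
    uncalibrated models, a synthetic-data generator emulating paired
    calibration and survey-only populations, and packaged summary tables from
    published COMSA-Mozambique / CHAMPS child and neonate analyses.
License: MIT
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
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
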