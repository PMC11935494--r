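Package: sltcfdna
Title: Donor-Derived Cell-Free DNA Surveillance Analysis for Single Lung Transplant
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing donor-derived cell-free DNA (dd-cfDNA)
    surveillance data from single lung transplant (SLT) recipients: the 2x
    single-lung correction and 1.0% positivity threshold, assignment of each
    blood draw to a diagnostic cohort (STABLE, AR, INFXN, CLAD, OTHER) or an
    exclusion from clinical events in a +/-6-week window, cohort-level
    Mann-Whitney comparisons with Benjamini-Hochberg false discovery rate
    control, and estimation of diagnostic performance (sensitivity,
    specificity, predictive values, likelihood ratios, AUROC) by
    within-patient subsampling to independence followed by bootstrap
    resampling with percentile confidence intervals. Includes a synthetic
    longitudinal cohort generator whose per-cohort dd-cfDNA distributions are
    lognormals quantile-calibrated to published medians and interquartile
    ranges, used to exercise every assignment and exclusion rule end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
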