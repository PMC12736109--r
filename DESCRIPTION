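Package: faerspv
Title: Disproportionality Signal Detection for FAERS Spontaneous Adverse
    Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FDA Adverse Event Reporting System (FAERS) style quarterly ASCII data:
    report assembly and identifier-based deduplication, primary-suspect
    cohort selection, 2x2 contingency tables at the MedDRA preferred-term
    and system-organ-class level, four disproportionality algorithms
    (reporting odds ratio, proportional reporting ratio, the Bayesian
    confidence propagation neural network information component, and the
    gamma Poisson shrinker relative reporting ratio) with a joint
    positivity rule, demographic and reporter-type subgroup scans, and
    time-to-onset analysis with cumulative incidence curves and Gray's
    K-sample test. A synthetic spontaneous-report generator with planted
    drug-event signals makes every stage testable without a database
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cmprsk,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
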