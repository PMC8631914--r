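Package: hfcea
Title: Markov Cohort Cost-Utility Modelling of SGLT2 Inhibitor Add-On
    Therapy in Heart Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cost-utility analysis of adding an SGLT2 inhibitor
    (dapagliflozin or empagliflozin) to standard treatment for heart
    failure with reduced ejection fraction, from the perspective of the
    Chinese health system. Implements a six-state Markov cohort model over
    NYHA functional classes with competing cardiovascular and
    age-dependent non-cardiovascular mortality, DEALE conversion of trial
    event proportions to per-cycle transition probabilities, half-cycle
    corrected discounting of costs and quality-adjusted life years,
    incremental cost-effectiveness statistics with WHO GDP-multiple
    categories, one-way and scenario sensitivity analyses, seeded
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and a patient-level microsimulation that serves
    as a brute-force oracle and synthetic-trial generator.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
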