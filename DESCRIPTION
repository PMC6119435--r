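Package: iriscea
Title: Cost-Utility Markov Model of the IRIS Domestic Violence Training and
    Advocacy Programme
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state Markov cohort model for cost-utility analysis of the
    IRIS (Identification and Referral to Improve Safety) general-practice
    training and advocacy programme for women experiencing domestic violence
    and abuse, compared with usual care. Implements deterministic cohort
    simulation over six-month cycles with half-cycle correction and
    discounting, prevalence calibration of the incidence transition, cost and
    QALY accrual under societal and NHS perspectives, incremental
    cost-effectiveness ratios with dominance handling, net monetary benefit,
    one-way (tornado) sensitivity analysis, and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves. Ships the pooled
    national parameter set as a validated plain-text fixture and a generator
    of structurally valid synthetic parameter sets for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    ggplot2
Config/testthat/edition: 3
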