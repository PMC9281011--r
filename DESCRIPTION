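Package: sepsiscost
Title: Claims-Based Sepsis Cohorts and Cost-Effectiveness Trend Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing sepsis cohorts from administrative
    hospital claims and analysing temporal trends in medical costs and
    cost-effectiveness. Implements a temporal rule-based sepsis case
    definition (new intravenous antibiotic therapy initiated within two
    days of a blood culture and continued for at least four consecutive
    days, combined with claims-level organ-dysfunction markers),
    infection-site assignment, consumer-price-index deflation and
    currency conversion of hospital costs, effective cost per survivor,
    yearly linear trend tests, subgroup analyses, and multivariable
    log-linear cost regression with multicollinearity diagnostics. A
    synthetic claims generator with known ground truth, calibrated to
    published yearly aggregates of the Japanese Diagnosis Procedure
    Combination (DPC) sepsis cohort 2010-2017, makes every stage of the
    pipeline testable without access to the restricted source database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
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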