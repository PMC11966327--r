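Package: akicea
Title: Cost-Effectiveness Modeling of Acute Kidney Injury Prevention
    Implementation Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort model for comparing
    implementation strategies that deploy a contrast-associated acute kidney
    injury (AKI) prevention protocol after cardiac catheterization. Patients
    branch on 7-day AKI, reach a 30-day disposition over four health states
    (normal kidney function, chronic kidney disease, end-stage renal disease,
    death), then progress through yearly Markov cycles stratified by AKI
    history, with discounted cost and quality-adjusted life-year accrual.
    Provides base-case evaluation with dominance, ICER and
    net-monetary-benefit ranking, one-way sensitivity analysis with tornado
    ordering, probabilistic sensitivity analysis with beta/gamma moment
    matching and cost-effectiveness acceptability curves, break-even
    threshold analysis on intervention cost, and a synthetic patient-level
    trial generator with parameter re-estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
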