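Package: ceameta
Title: Meta-Analysis of Study-Level Cost-Effectiveness Evaluations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for synthesizing published health-economic evaluations at
    the study level: currency harmonization via consumer-price-index
    inflation and purchasing-power-parity conversion, per-study incremental
    cost-effectiveness ratios and net monetary benefit at willingness-to-pay
    thresholds, descriptive and subgroup summaries, inverse-variance fixed-
    and random-effects pooling with DerSimonian-Laird between-study variance,
    log-scale pooling of ratio outcomes, unweighted OLS meta-regression with
    added-variable diagnostics, Egger regression for funnel-plot asymmetry,
    leave-one-out sensitivity analysis, and a synthetic study-level data
    generator with known ground truth for method validation. Ships a
    transcribed 17-observation dataset of economic evaluations of the
    lipid-lowering agent inclisiran versus standard of care.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
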