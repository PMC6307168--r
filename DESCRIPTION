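Package: trialcea
Title: Trial-Based Cost-Utility and Cost-Effectiveness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for economic evaluation alongside two-arm randomised trials:
    quality-adjusted life years by area-under-the-curve, multi-category costing
    of healthcare use, medication and absenteeism under societal and healthcare
    perspectives, multiple imputation of missing costs and effects by chained
    equations with Rubin's rules pooling, seemingly unrelated regression of
    cost and effect differences with data-driven confounder selection,
    bias-corrected and accelerated bootstrap confidence intervals, incremental
    cost-effectiveness ratios, cost-effectiveness planes and acceptability
    curves. Includes a seeded synthetic-trial generator with known ground truth
    for validation, calibrated to a telephone-based weight-loss trial in knee
    osteoarthritis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
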