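Package: trialcea
Title: Trial-Based Cost-Effectiveness Analysis with Bootstrap Probabilistic
    Sensitivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A patient-level pipeline for trial-based economic evaluation of
    critical-care interventions: synthetic two-arm cohort generation with
    two-piece exponential survival, heavy-tailed hospital costs and
    longitudinal utility interviews; unit-cost weighting of post-discharge
    resource use; quality-adjusted survival from the area under the utility
    curve; life-table lifetime projection with annual discounting; and
    bootstrap Monte Carlo probabilistic sensitivity analysis producing
    incremental cost-effectiveness clouds, dominance and willingness-to-pay
    threshold probabilities, acceptability curves, confidence ellipses,
    subgroup analyses and one-way sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    survival,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
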