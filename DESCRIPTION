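Package: cuatree
Title: Cost-Utility Analysis with Decision Trees and Sensitivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-tree cost-utility analysis for two-arm comparisons of
    care pathways, built around a hospital pharmaceutical-care evaluation:
    per-arm expected costs and quality-adjusted life year (QALY) decrements,
    incremental analysis (ICER, net monetary benefit, dominance
    classification), one-way deterministic sensitivity analysis with tornado
    ordering, and probabilistic sensitivity analysis with method-of-moments
    beta/gamma hyperparameterisation and cost-effectiveness acceptability
    curves. Includes the upstream stages: pharmacist labour costing from
    salary and working-calendar inputs, nonparametric bootstrap of means with
    percentile confidence intervals, and a synthetic patient-level cohort
    generator so the whole pipeline runs end-to-end without external data.
License: MIT
Encoding: UTF-8
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
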