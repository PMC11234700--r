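Package: ceatree
Title: Decision-Tree Cost-Utility Analysis with Deterministic and Probabilistic Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-tree engine for cost-utility analysis in health
    economics. Models are declared as a decision root over treatment
    strategies, chance nodes with probability expressions, and terminal
    cost/utility payoffs; the engine rolls the tree back to expected cost
    and quality-adjusted life years per strategy and derives incremental
    cost-effectiveness ratios, net monetary benefit and the
    willingness-to-pay decision rule. Includes one-way, two-way, tornado
    and threshold (bisection) sensitivity analysis, probabilistic
    sensitivity analysis with method-of-moments beta/gamma samplers,
    cost-effectiveness acceptability curves and cost-effectiveness plane
    confidence ellipses, plus linear calibration of terminal payoffs to
    arm-level targets. Ships a calibrated model comparing early anterior
    cruciate ligament reconstruction with conservative treatment in
    Indonesia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
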