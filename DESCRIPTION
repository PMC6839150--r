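Package: roscore
Title: Points-Based Gene-Expression Risk Scoring for Survival Cohorts
Version: 0.1.0
Authors@R:
    person("Ovarian Signature", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a reactive-oxygen-species (ROS) themed, points-based
    prognostic scoring pipeline for gene-expression survival cohorts:
    per-gene median dichotomization with log-rank screening and
    direction-of-effect assignment, summation of favorable-side points into a
    per-patient integer score, equal-range splitting into low/high risk
    groups, and evaluation by Kaplan-Meier curves, log-rank tests, univariate
    and multivariable Cox proportional-hazards regression, score versus
    median-survival Pearson correlation, and censoring-aware ROC analysis of
    binarized survival. All survival statistics are implemented from first
    principles. A seeded synthetic-cohort generator with known ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    survival,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
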