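Package: uaeopt
Title: Design-of-Experiments Optimization of Ultrasound-Assisted
    Extraction Yields
Version: 1.0.0
Authors@R:
    person("Analytics", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for optimizing multi-analyte extraction processes with
    designed experiments. Builds Box-Behnken designs for 3 to 7 factors,
    scores multiple analyte yields into a single composite response via
    precedence-chart weights, fits second-order response-surface models
    with a complete ANOVA (lack-of-fit partition, PRESS-based predicted
    R-squared), trains least-squares support vector machine regressions
    with cross-validated RBF hyperparameter search, maximizes either
    fitted surface over the design cube, and compares candidate models by
    validation relative deviation. Includes radical-scavenging assay
    arithmetic, linear calibration utilities, a synthetic-data generator
    for the assumed quadratic-plus-noise data model, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
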