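Package: fdqp
Title: Federated Data Quality Profiling for Multi-Edge Patient Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Data-quality profiling for patient-monitoring data held at
    multiple edge nodes. Builds versioned, XML-serializable data quality
    profiles (attributes, weights, dimensions, tolerances, rules, measures),
    repairs data with a configurable rule table (mean/median/mode/KNN/multiple
    imputation, column and row drops), federates edge profiles at a server
    with quality-based node elimination and rank-aggregation feature
    selection, and quantifies the accuracy impact of profiling with a
    Gaussian-kernel most-similar-patient evaluation harness. Includes a
    synthetic multi-edge cohort generator with controlled MCAR/MAR/MNAR
    missingness, outlier injection, and node corruption so the full pipeline
    is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    e1071,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
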