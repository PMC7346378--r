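Package: strokeppm
Title: Predictive Process Monitoring for Stroke Thrombolysis Decision Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Outcome-oriented predictive process monitoring for acute ischemic
    stroke thrombolysis decisions. Reads clinical event logs (one timestamped
    activity per row plus per-case static attributes), extracts prefix logs
    from completed traces, encodes prefixes into fixed-length feature vectors
    (control-flow frequency counts, static case attributes, last-state event
    attributes), and trains decision-tree and random-forest outcome
    classifiers with per-class evaluation metrics. A computable rule engine
    encodes the rt-PA intravenous thrombolysis eligibility criteria
    (indications and contraindications within the 3-hour window) as a
    declarative rule set, produces explainable recommendations, and labels
    cohort conformance into the four recommendation-by-treatment quadrants.
    A synthetic stroke-cohort generator with configurable prevalence,
    guideline-nonconformance rate and class-dependent activity emission makes
    every component testable without access to protected patient records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rpart,
    ranger,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
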