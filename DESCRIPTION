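Package: egressr
Title: Egress Dynamics of Ants Escaping a Single-Exit Chamber
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for single-exit egress experiments with ants
    driven by a repellent: inter-escape (headway) interval statistics, the
    exponential-decay interval-frequency model, cumulative escape-curve fits,
    expectation-threshold group (burst) segmentation with the group flow-rate
    statistic, pairwise comparison statistics with star annotation, and a
    seeded synthetic egress generator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    readr,
    readxl,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
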