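Package: gaitfs
Title: Multi-Objective Feature Selection for Gait Mode Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing compact user-intent-recognition systems for
    lower-limb prostheses. Implements gradient-based multi-objective feature
    selection (GMOFS): an elastic-net-regularized constrained multilayer
    perceptron whose per-feature input multipliers rank features, swept over a
    regularization grid to trace a subset-size versus cross-validation-error
    Pareto front. Also provides four multi-objective biogeography-based
    optimization variants (vector-evaluated, non-dominated-sorting,
    niched-Pareto, strength-Pareto) over binary feature masks, Pareto-front
    quality metrics (normalized hypervolume, relative coverage), sliding-window
    segmentation of multichannel gait recordings, canonical time- and
    frequency-domain feature extraction, cross-validation protocols, and
    majority-vote label smoothing under a real-time latency constraint.
    Includes a synthetic-data module so the whole pipeline is testable without
    subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
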