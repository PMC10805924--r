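Package: acvsadapt
Title: Adaptive-Choice Visual Search: Schedules, Adaptation Curves, and
    Hierarchical Bayesian Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing adaptive-choice visual search (ACVS)
    experiments in which two always-present targets are embedded among
    distractors whose shape ratio changes systematically over trials.
    Builds plateau/transition trial schedules and search displays, models
    target choice with a three-parameter adaptation curve (adaptation tau,
    shift delta, bias beta), fits the curve at group and participant level
    with a hierarchical Bayesian Bernoulli model (via JAGS), summarises
    posteriors by modes and highest-density intervals, compares reaction
    times between cycle phases with the BEST two-group procedure, analyses
    eye-fixation data (nearest-item assignment, normalized shape
    proportions, chosen-shape analyses), and simulates complete synthetic
    studies with known ground truth so every pipeline stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
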