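Package: wfsmooth
Title: Temporal Smoothing and Stability Evaluation for Surgical Workflow
    Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-hoc stabilisation and evaluation of frame-wise surgical
    workflow predictions sampled at 1 Hz. Implements two causal temporal
    smoothing functions (a sliding-window modal filter and a hysteresis
    threshold filter), a supervised discrete hidden Markov model
    post-processor decoded online with a fixed lookahead, training-set
    window-size selection, and an evaluation suite built around prediction
    volatility (the ratio of predicted to ground-truth class changes) and
    support-weighted F1. A semi-Markov workflow simulator with
    neighbour-biased misclassification and occlusion-burst noise provides
    reproducible synthetic benchmarks, and a command-line interface wires
    simulation, smoothing, tuning and evaluation into scripted runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
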