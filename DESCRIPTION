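Package: tsmsa
Title: Time-Resolved Multi-Perturbation Shapley Value Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes a network's output time series into per-node causal
    contribution time series using multi-perturbation Shapley value analysis
    (MSA): a permutation-sampling estimator of time-resolved Shapley values in
    which coalitions of nodes are virtually lesioned and the outcome of each
    lesion configuration is contrasted to isolate marginal contributions.
    Ships the testbeds needed to study the dissociation between a node's
    recorded activity and its causal contribution: banks of sinusoidal toy
    signals with linear, scaled and saturating readouts, a fixed-step
    integrator for the Mackey-Glass delay differential equation, and
    leaky-integrator echo state networks (ESNs) trained in generative mode on
    chaotic time-series prediction and in driven mode on a tunable
    frequency-generator task. Includes reconstruction and
    contribution-activity correlation diagnostics, broom-style tidiers and
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
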