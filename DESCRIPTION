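Package: visfield
Title: Dynamic Neural Field Simulation of Low-Contrast Visibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the stabilization of visibility for near-threshold,
    low-contrast line segments with a stochastic two-layer (excitatory and
    inhibitory) dynamic neural field augmented by a memory trace, input
    adaptation, and a slow Ornstein-Uhlenbeck resting-level fluctuation.
    Ships generators for ten psychophysical protocols (simultaneous
    object/probe pairs, delayed probes, repeated relocations at constant
    contrast, ascending and descending contrast ladders under the modified
    method of limits, blank-interval and brief-frame variants, and a
    distance-dependent threshold staircase), a model observer that scores
    per-frame visibility and switch events, a seeded Monte-Carlo experiment
    runner with component ablations, and analysis routines for switch-rate
    curves, constant-switch-probability fits, hysteresis gaps, and
    psychometric tables.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
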