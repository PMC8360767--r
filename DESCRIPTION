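Package: oscivm
Title: Action-Locked Theta Oscillations in Behavior and Event-Related BOLD
Version: 1.0.0
Authors@R:
    person("oscivm", "developers", email = "oscivm@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of theta-range oscillations synchronized
    to a voluntary action, at the level of both behavior and region-of-interest
    BOLD time series. Provides a synthetic-data generator for visuo-motor delay
    experiments (Bernoulli trial outcomes with sinusoidally modulated accuracy,
    and two-ROI event-related BOLD runs built from a forward hemodynamic
    model), sinusoidal regression of binned accuracy with a permutation-
    corrected free-frequency fit and a Hotelling T-squared group test, finite
    impulse response (FIR) deconvolution GLMs for delay-resolved hemodynamic
    responses with repeated-measures and Holm-corrected paired contrasts,
    residual-based V1-M1 functional connectivity with bootstrap inference, and
    a gamma-family forward model of the visuo-motor BOLD response with visual
    gain estimation. A command-line pipeline ties the stages together into a
    reproducible run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
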