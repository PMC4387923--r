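Package: songcircuit
Title: Circular Rate-Model Simulation of Canary Song Respiratory Motor Control
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates a four-population additive (firing-rate) neural network
    model of the songbird respiratory motor pathway: an expiratory-related
    brainstem area (excitatory/inhibitory pair) driven directly by a square
    pulse from a brainstem initiating area and, with a delay, by the same
    pulse after telencephalic processing through nucleus RA. Ships the named
    parameter presets that reproduce the four canonical canary air-sac
    pressure patterns (P0, pulsatile, P2, P1), a deterministic fixed-step
    Runge-Kutta integrator for the pulse-driven non-autonomous system,
    equilibrium finding, an HVC-cooling experiment (pulse stretching and
    delay) that stretches and breaks P0 patterns, and feature extraction for
    pressure-like traces (prominence-based extrema, pulse segmentation
    against a phonation threshold, dominant period, amplitude trend, and a
    rule-based pattern classifier).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
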