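Package: hjfret
Title: Single-Molecule FRET Analysis of Four-Way DNA Junction Biosensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for single-molecule FRET
    (smFRET) experiments with distance-tuned four-way (Holliday) DNA
    junction biosensors. Generates synthetic two-state Markov-switching
    donor/acceptor intensity traces and dual-channel TIRF movies, extracts
    per-molecule traces by aperture photometry, computes FRET efficiency
    with photobleach and acceptor-verification quality control, separates
    dynamic (target-bound) from static molecules by digital counting, fits
    a two-state Gaussian hidden Markov model to truncated-and-stitched
    trace windows, derives dwell times, transition rates and equilibrium
    constants, builds transition density plots, assigns molecules to
    sensors by their FRET-state pair for multiplexed detection, and builds
    dose-response calibration curves with a limit-of-detection call.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
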