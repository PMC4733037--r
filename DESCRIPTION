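Package: unblockr
Title: Single-Unit and Behavioral Analysis of Pavlovian Unblocking Sessions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-unit recordings collected during an
    odor-guided Pavlovian unblocking task, in which novel cues signal an
    upshifted, downshifted, or unchanged (blocked) reward. Provides a validated
    session container with JSON/CSV serialisation, peri-event firing-rate
    statistics (inter-trial-interval baseline, odor-epoch rates, normalized
    firing, binned and sliding-window rate estimates), a functional taxonomy of
    cue-responsive neurons (value-coding, cue-tuned, predictive, salience,
    sensory) based on epoch t-test screens, trial-resolved sliding-window
    significance maps, pseudo-ensemble linear decoding of trial type with exact
    binomial significance, factorial behavioral analyses of response latency
    and time in the reward well, and an inhomogeneous-Poisson synthetic session
    generator with ground-truth unit labels so the full pipeline can be
    exercised and calibrated without recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), MASS, nnet, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
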