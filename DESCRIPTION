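Package: mtsdecode
Title: Time-Resolved Neural Decoding for Delayed Match-to-Sample Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of primate delayed match-to-sample
    electrophysiology sessions. Generates synthetic multichannel local field
    potential (LFP) recordings with known injected stimulus-, match- and
    motor-related signal components; preprocesses continuous recordings
    (notch, low-pass, resampling, band-pass, clipping checks, event-locked
    epoching); computes signal-detection behavioral statistics (d-prime by
    mismatch contrast, reciprocal-latency reaction-time tests); and runs
    covariate-balanced, cross-validated, time-resolved linear support vector
    machine decoding with permutation-based significance and onset-latency
    inference, including between-condition contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
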