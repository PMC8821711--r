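Package: stereopam
Title: Stereo Passive Acoustic Monitoring of Sperm Whale Clicks
Version: 0.1.0
Authors@R: person("PAM", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for passive acoustic monitoring of sperm
    whales with a two-hydrophone (stereo) antenna: synthetic-scene
    generation with ground truth, Teager-Kaiser click detection,
    inter-channel time-difference-of-arrival tracking into passages and
    individual counts, a small depthwise convolutional click classifier
    with a recall-versus-SNR model, cepstral inter-pulse-interval body
    size estimation, octave-band ambient noise measurement with
    Wenz-curve calibration, a Monte-Carlo effective-detection-area model,
    and cue-density estimation, plus the nonparametric test battery used
    to analyse such surveys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
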