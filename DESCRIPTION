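Package: farrowcam
Title: Acoustic-Camera Simulation and Validation for Farrowing Sows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying sound-camera monitoring of farrowing sows.
    Simulates farrowing acoustic scenes in an instrumented pen (timed, located
    sound events, sow behaviour scripts, and multichannel microphone-array
    signals), localises sound sources by delay-and-sum beamforming into
    "sound spots", matches spot streams against reference annotations of
    audible sounds and behaviour under tolerance-window rules, computes the
    associated validation metrics (accuracy, error, sensitivity, specificity,
    precision), and detects farrowing onset and progress from spot patterns
    (cessation of rooting near the sow's head, piglet-movement spots behind
    the sow).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
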