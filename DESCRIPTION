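Package: triggerbench
Title: Discrete-Time Emulation and Timing Validation of a Programmable
    Trigger Box
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Software emulation of a microcontroller-based event
    synchronization device ("trigger box") and of the measurement bench
    used to characterize its timing.  Implements the firmware's
    threshold-onset state machine with minimum pulse duration, pulse
    increment (hold time) and refractory gating, switch de-bouncing, a
    whole-device model with analog front-ends, ADC quantization and
    strictly sequential per-channel scanning, seeded generators for the
    validation stimuli (abrupt-onset tones, noise bursts, auditory oddball
    sequences), a virtual digitizer, onset detection with Woody-style
    epoch realignment, latency/jitter/pulse-duration statistics, and a
    demonstration of how stimulus-timing jitter smears time-locked
    event-related-potential averages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
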