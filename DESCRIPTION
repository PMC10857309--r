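Package: cogvergence
Title: Cognitive Vergence Analysis of Binocular Eye-Tracking Oddball Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify event-locked convergence eye movements
    ("cognitive vergence") from binocular gaze recordings collected during a
    visual oddball task. Provides readers and writers for timestamped
    left/right-eye gaze samples with tracker validity codes, trial
    segmentation with validity-based exclusion and interpolation onto a
    uniform grid, conversion of on-screen gaze coordinates to vergence
    angles, the per-trial relative vergence modulation curve V(t),
    condition-averaged response curves, windowed response measures
    (initial, peak, delay), per-subject target/distractor modulation
    indices, group comparisons, and a seedable simulator of binocular
    oddball sessions for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
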