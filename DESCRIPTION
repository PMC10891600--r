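Package: gaitfbf
Title: Heading-Invariant Gait Phase Recognition with a Floating Body-Fixed
    Frame and a Bidirectional LSTM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognises the four sub-phases of the human gait cycle (swing,
    heel strike, full contact, heel off) from wearable inertial sensors in a
    way that is robust to the walking direction and to how the sensors were
    strapped on.  Implements a stand-stoop sensor-to-segment calibration that
    builds a body-fixed anatomical frame, carries that frame along with the
    waist sensor so all distal sensor streams are expressed heading-free
    (the "floating body-fixed frame"), labels samples from three-channel
    force-sensitive-resistor insole contacts, preprocesses features by
    Gaussian noise-injection augmentation, standardization and a
    sliding-window label-overlapping encoder, classifies windows with a
    bidirectional LSTM trained by backpropagation through time, and selects
    hyperparameters with an L18 orthogonal-array level-average analysis.
    Ships a synthetic gait simulator (IMU + insole contacts + calibration
    gesture) so the whole pipeline is testable without recorded subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
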