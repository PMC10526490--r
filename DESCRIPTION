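Package: eegemo
Title: EEG Emotion Recognition with Deformable Convolutional Attention Networks
Version: 0.1.0
Authors@R: person("EEG", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for emotion recognition from multi-channel EEG. Extracts
    differential-entropy features per frequency band (theta, alpha, beta,
    gamma) from 1-s windows, arranges them on a 9x9 scalp grid into 3D feature
    tensors, and classifies them with a residual convolutional network that
    combines deformable convolution, efficient channel attention, bottom-up
    feature-pyramid fusion and a bidirectional GRU head. Includes a synthetic
    EEG generator with known class structure, k-fold and leave-one-subject-out
    evaluation, standard classification metrics, and readers and writers for a
    plain-text recording container and EDF files. The full network stack
    (forward and backward passes) is implemented in base R and runs on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
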