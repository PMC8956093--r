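Package: icegait
Title: Slip Detection and Classification for Walking on Icy Level and Inclined Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated detection and classification of slips from foot marker
    trajectories recorded during walking on level and inclined ice surfaces.
    Implements zero-lag Butterworth preprocessing of marker positions, stride
    segmentation from heel vertical velocity (toe-off and heel-contact event
    detection), extraction of 36 hand-crafted kinematic features per step,
    histogram-overlap feature selection, and two one-vs-rest linear support
    vector machine classifiers that label each step under a toe-slip and a
    heel-slip taxonomy (backward/forward toe slips, backward/forward heel
    slips) plus a derived binary slip decision. Includes leave-one-subject-out
    cross-validation with random under-sampling of the majority class,
    Bland-Altman event-timing validation, an event-timing sensitivity
    analysis, and a synthetic gait generator that reproduces the six step
    morphologies needed to exercise the whole pipeline without access to
    motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
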