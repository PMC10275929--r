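Package: physioaffect
Title: Real-Time Affective State Estimation from Wearable Physiological
    Signals
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Window-based estimation of affective states on the
    valence-arousal plane from galvanic skin response, electrocardiogram
    and respiration-rate recordings. Provides zero-phase Butterworth
    preprocessing with tonic/phasic electrodermal decomposition, R-peak
    detection and time-domain heart-rate-variability measures, extraction
    of 23 named physiological features on 0.5-second windows, ReliefF
    feature weighting with a cross-participant median-positive selection
    rule, quadrant-based binary and multi-class classification
    (k-nearest-neighbours, cubic and Gaussian support vector machines,
    linear discriminant analysis) with leave-one-image-per-class-out
    evaluation and estimation-time measurement, and a seeded synthetic
    cohort generator emulating a picture-viewing stimulation protocol so
    the whole pipeline can be exercised without human recordings.
License: MIT + file LICENSE
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
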