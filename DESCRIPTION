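Package: qrsdetect
Title: Adaptive-Threshold QRS Complex Detection for ECG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects QRS complexes (R-wave fiducials) in electrocardiogram
    recordings with an adaptive-threshold algorithm. The detector chains a
    five-stage preprocessing cascade (recursive low-pass, high-pass,
    five-point derivative, squaring, moving-window integration), a
    half-drop candidate peak finder, and an adaptive signal/noise peak
    threshold with RR-interval tracking and threshold-halving search-back
    for missed beats. Includes a reader and writer for WFDB-format records
    and annotations (MIT-BIH Arrhythmia Database layout), a seeded
    synthetic ECG generator with ground-truth beat locations, flagging of
    abnormally long RR intervals, RR-Lorenz (Poincare) plot data, and
    beat-level evaluation (sensitivity, positive predictivity, detection
    rate) against reference annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
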