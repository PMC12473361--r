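Package: regcar
Title: Cerebral Autoregulation Assessment from Rheoencephalography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing dynamic cerebral autoregulation from
    rheoencephalography (REG, pulsatile cerebral bioimpedance) recorded with a
    wearable headband together with continuous arterial blood pressure.
    Implements decoding of the headband's framed hex-text capture format,
    zero-phase Butterworth baseline-drift removal, cardiac-cycle detection and
    validation, cubic-spline time normalization and ensemble averaging into a
    standardized REG waveform, per-cycle area under the curve, beat-to-beat
    blood pressure metrics, a template-correlation recovery-curve statistic for
    counting cycles to hemodynamic recovery after a sit-to-stand maneuver, and
    identification of a first-order linear time-invariant autoregulation model
    yielding the time constant tau and gain G with free-run goodness of fit.
    A seeded generator of coupled pressure/impedance recordings with known
    ground truth supports validation without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
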