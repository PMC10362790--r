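Package: ppgvitals
Title: Non-Invasive Blood Pressure and Oxygen Saturation Estimation from
    Photoplethysmogram Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end framework for estimating arterial systolic and
    diastolic blood pressure and peripheral oxygen saturation (SpO2) from
    photoplethysmogram (PPG) waveforms. Provides ICU-style waveform quality
    control (flat-run handling, Hampel filtering of beat-wise pressure
    extrema, zero-phase Butterworth band-pass filtering, beat-cycle
    detection, 20-second slicing with anomalous-cycle gating), empirical
    mode decomposition into multichannel model inputs, an encoder-only
    time-series transformer with learnable positional encodings trained by
    masked-reconstruction pre-training and per-patient chronological
    fine-tuning, AAMI and BHS device-compliance grading, and a synthetic
    PPG/ABP/SpO2 cohort generator with known ground truth for validating
    every stage without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
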