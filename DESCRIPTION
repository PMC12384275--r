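Package: cardiofuse
Title: Multimodal Cardiorespiratory Monitoring from Arm-Worn PPG, Bioimpedance and Single-Sided ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing pipeline for heart-rate and breathing-rate
    estimation from an arm-worn multimodal wearable combining three-wavelength
    photoplethysmography (PPG), bioimpedance plethysmography (BioZ) and
    single-sided ECG (SS-ECG). Provides a synthetic recording simulator with
    known cardiac and respiratory ground truth (respiratory sinus arrhythmia,
    amplitude modulation, baseline wander, skin-tone dependent PPG attenuation,
    EMG bursts, motion transients and electrode pop-off), modality-specific
    zero-phase Butterworth preprocessing, sliding-window heart-rate estimation
    (inter-beat intervals for ECG channels, spectral peaks for pulsatile
    channels) with physiological validity gating, a skin-tone conditioned
    hierarchical heart-rate fusion, fourteen-channel breathing-rate feature
    extraction (baseline wander, amplitude modulation, frequency modulation),
    bagged-tree and robust-linear breathing-rate fusion models, and
    leave-one-subject-out evaluation with robustness (R1/R2) and mean absolute
    error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
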