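Package: lungvib
Title: Contact-Free Lung-Congestion Detection from Chest-Wall Vibration Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting pulmonary congestion
    from single-channel chest-wall vibration recordings. Generates synthetic
    cohorts with quasi-periodic S1/S2 heart-sound wavelets, respiratory
    modulation and a planted inhale-phase congestion signature; detects
    heart-sound and respiratory-phase landmarks; extracts landmark-sectioned
    time and spectrogram band features; trains a decision-stump AdaBoost
    classifier with a calibrated inconclusive zone; and evaluates diagnostic
    accuracy (sensitivity, specificity, predictive values, likelihood ratios,
    ROC/AUC) with subject-grouped cross-validation and bootstrap confidence
    intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
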