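Package: cwtcardio
Title: Wavelet-Based Cardiac Alteration and Electrodermal Stress Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing single-lead wearable electrocardiogram (ECG)
    and skin conductance response (SCR) recordings. Detects R peaks with a
    continuous wavelet transform (Coiflet-5 mother wavelet) and windowed
    normalized thresholding, classifies premature beats (extrasystoles) and
    arrhythmic RR transitions with ratio rules on inter-beat intervals,
    resamples heart-rate variability with shape-preserving cubic Hermite
    interpolation, converts skin resistance through a voltage-divider model,
    trains per-user gain-ratio (C4.5-style) decision trees for stress versus
    relax classification of SCR samples, and computes confusion-matrix
    diagnostics (sensitivity, specificity, accuracy, correct rate). Includes a
    synthetic ECG/SCR generator with ground-truth annotations so every stage is
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
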