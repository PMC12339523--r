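Package: pulsefuse
Title: Fused Wrist Pulse and ECG Analysis for Coronary Heart Disease Group Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of synchronously acquired wrist
    pressure pulse wave (PPW) and limb-lead ECG recordings, aimed at
    multi-class identification of coronary heart disease and its
    comorbidities (hypertension, type 2 diabetes). Provides a calibrated
    synthetic two-channel signal generator with exact ground-truth
    fiducials, Butterworth and cubic-spline preprocessing, pulse and
    P-QRS-T fiducial delineation, time-domain feature extraction
    (amplitude ratios, pulse widths, systolic/diastolic areas, pulse-rate
    and heart-rate variability), group-comparison statistics with
    chi-square power analysis, SMOTE class balancing, and grid-searched
    random-forest, bagged-tree and support-vector benchmarking with
    importance-ranked sequential forward feature selection under
    stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
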