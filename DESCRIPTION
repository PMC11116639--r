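Package: snoregrade
Title: Obstructive Sleep Apnea Severity Grading from Overnight Snoring Audio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for automatic grading of obstructive
    sleep apnea-hypopnea syndrome (OSAHS) severity from overnight snoring
    recordings. Extracts per-minute Mel-frequency cepstral coefficients
    (MFCC) from mono PCM WAV audio, transforms them into semantic feature
    vectors via a pluggable sentence encoder with a deterministic
    download-free fallback, derives per-minute binary apnea-event labels
    from interval annotations under a 30-second rule, trains a gradient
    boosted tree classifier to detect apnea minutes, aggregates predictions
    into an apnea-hypopnea index (AHI), and grades nights into four
    severity classes (normal, mild, moderate, severe). Includes a synthetic
    overnight-audio simulator with ground-truth annotations so the full
    pipeline is testable without clinical data, plus evaluation metrics
    (precision, recall, F1, specificity, ROC/AUC, MAE, MSE, R-squared) and
    permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
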