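Package: neoseizr
Title: Neonatal EEG Seizure Detection with Aquila-Optimized Gradient Boosting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for neonatal electroencephalography (EEG)
    seizure detection: EDF recording and per-second annotation input/output, a
    synthetic neonatal EEG generator with injected ictal spike-wave bursts,
    signal preprocessing (channel selection, anti-aliased downsampling,
    zero-phase high-pass filtering, min-max scaling, fixed-length windowing and
    threshold-based window labeling), extraction of fifteen time- and
    entropy-domain features per window (summary statistics, Hjorth parameters,
    permutation, Shannon, approximate and sample entropy), a population-based
    Aquila Optimizer in both its original form and a modified variant with an
    epoch-decaying search control factor, hyperparameter tuning of a
    gradient-boosted tree classifier over a seven-dimensional search space by
    minimizing one minus classification accuracy, and binary-classification
    evaluation (confusion matrix, accuracy, AUC, F1, Cohen's kappa,
    sensitivity, specificity, ROC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    xgboost,
    rpart,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
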