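Package: seizAdapt
Title: Patient-Adaptive Neonatal Seizure Detection by Confidence-Weighted
    MAP Adaptation of Gaussian Mixture Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a patient-adaptive neonatal EEG seizure detection
    framework. A fixed patient-independent discriminative classifier (a
    calibrated kernel margin classifier) supplies per-epoch seizure
    probabilities that drive on-the-fly, confidence-weighted maximum
    a-posteriori (MAP) adaptation of per-class Gaussian mixture models;
    the adapted generative classifier is fused with the discriminative one
    by the geometric mean. Includes a synthetic cohort generator emulating
    long multichannel neonatal EEG feature streams with rare seizure
    events, epoch-based ROC metrics (AUC and specificity-restricted AUC90),
    a correlated-ROC significance test, event-based detection metrics, and
    a leave-one-patient-out streaming hourly-adaptation harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
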