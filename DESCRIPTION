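Package: apneamodes
Title: Sleep Apnea Screening from Single-Lead ECG via Empirical Mode
    Decomposition and a 1D Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for minute-by-minute sleep apnea screening from overnight
    single-lead electrocardiogram (ECG). Implements the full processing chain:
    a synthetic generator of apnea-like ECG with cyclic bradycardia-tachycardia
    and QRS amplitude modulation, PhysioNet-style record input/output,
    FIR band-pass preprocessing and 60-second segmentation with quality
    screening, empirical mode decomposition (EMD) into intrinsic mode
    functions with combination features (IMF1, IMF2, IMF12, IMF123), complex
    Morlet continuous wavelet scalograms, neighborhood component analysis
    (NCA) feature selection, SMOTE/ROS/RUS class rebalancing, a seeded 1D
    deep convolutional network trained with Adam on cross-entropy, and
    segment-level (k-fold) plus subject-level (leave-one-subject-out)
    evaluation with ROC/AUC and Youden's index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    png,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
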