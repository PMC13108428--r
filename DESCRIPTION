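Package: cardiopain
Title: ECG-Based Objective Pain Assessment with Explainable Cascade Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates thermal-pain ECG sessions with a continuous 0-100 pain
    rating (CoVAS) and known autonomic ground truth, segments them into
    stimulus-aligned analysis windows, extracts a multi-domain battery of ECG
    and heart rate variability biomarkers (signal statistics, time-, frequency-
    and geometric-domain HRV), and fits a dual-layer cascade model: a random
    forest classifier for pain presence gating a conditional random forest
    regressor for pain intensity. Ships a full explainability suite (exact and
    tree-path Shapley values, partial dependence and individual conditional
    expectation curves, Gini and permutation importance, Pearson correlation,
    depth-limited global surrogate rules) and agreement/metric evaluation
    including Bland-Altman limits of agreement and pain-severity-stratified
    performance.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    rpart,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
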