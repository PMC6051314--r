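Package: dfncstates
Title: Dynamic Functional Network Connectivity States and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for dynamic functional network connectivity (dFNC) analysis
    of component time courses from resting-state fMRI: Butterworth band-pass
    filtering, tapered sliding-window Pearson connectivity, k-means
    decomposition of windowed connectivity into recurring brain states with
    elbow-based model selection, per-state mass-univariate group statistics
    with false discovery rate control, and state-aware classification with a
    least-squares linear support vector machine under nested leave-one-out
    cross-validation. Includes a synthetic cohort generator with hidden
    state-switching covariance structure for validating every stage of the
    pipeline, and a bootstrap comparison of dynamic versus static
    connectivity classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
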