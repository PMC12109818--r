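Package: stentropy
Title: Stockwell Entropy and Common Spatial Patterns for EEG Emotion
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature extraction and classification of multichannel EEG by
    sliding-window differential entropy in the Stockwell (S-)transform
    time-frequency domain ("Stockwell entropy"), combined with common
    spatial pattern (CSP) spatial filtering.  Provides an FFT-based discrete
    S-transform with frequency-adaptive Gaussian windows, grouping of
    coefficients into the canonical EEG bands (Delta to Gamma), sliding
    differential entropy, CSP fitting by generalized eigendecomposition with
    one-vs-rest multiclass support, stratified cross-validation and holdout
    evaluation with RBF-SVM and random-forest back ends, a synthetic EEG and
    test-signal generator, and a simulation study of how signal frequency
    and amplitude drive the stability of Stockwell entropy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    signal,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
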