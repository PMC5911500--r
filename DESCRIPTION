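Package: fccr
Title: Feature-Compressing Channel Ranking for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Channel selection and classification for epoched multichannel
    motor-imagery EEG. Per-channel features (autoregressive band spectral
    power or log-variance time-domain parameters) are pooled over training
    trials and channels, compressed by k-means into integer cluster
    signatures forming a trials-by-channels matrix, and channels are ranked
    by the row norms of weight matrices fitted by three convergent
    row-sparse selection algorithms: l2,1-norm robust feature selection
    (iteratively reweighted), robust unsupervised feature selection with a
    graph Laplacian and nonnegative factors, and forward-backward greedy
    structural sparse least-squares regression. Classification of held-out
    trials uses regularized linear discriminant analysis on the original
    features of the selected channels under a repeated stratified
    cross-validation protocol, with a synthetic band-power generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
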