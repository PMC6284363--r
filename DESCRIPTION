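Package: ictalcnn
Title: Seizure Stage Classification from Multi-Channel EEG with 3D Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for automatic epileptic seizure detection from
    annotated multi-channel scalp EEG. Recordings are labeled into inter-ictal,
    pre-ictal and ictal stages, cut into non-overlapping fixed-length windows,
    rasterized per channel into square grayscale images, stacked into 3D volumes
    with channels ordered by inter-channel correlation, and classified with a
    3D-kernel convolutional network (a 2D network is provided as a baseline).
    Includes a deterministic synthetic EEG generator emulating the three
    electrographic regimes, EDF input/output, a from-scratch CNN engine with
    group and batch normalization, Adam optimization with a two-rule learning
    rate schedule, k-fold cross-validation, and one-vs-rest evaluation metrics
    with published reference confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    yaml
Config/testthat/edition: 3
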