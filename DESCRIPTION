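Package: fmriSTC
Title: Spatiotemporal Window-Vote Classification of 4D fMRI Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for binary classification of subjects from 4D
    resting-state fMRI volumes. Per-time-point spatial features are extracted by a
    multi-scale two-layer 3D convolutional encoder, sliding-window temporal
    dynamics by a long short-term memory (LSTM) encoder, and the concatenated
    per-window features are classified by gradient-boosted decision trees, with an
    odd-window majority vote deciding the subject label. Includes a seeded
    synthetic 4D cohort generator with class-dependent spatiotemporal signal and
    injectable motion, the standard resting-state preprocessing chain (intensity
    normalization, global signal regression, band-pass filtering, framewise-
    displacement quality control), subject-level stratified cross-validation with
    contingency metrics, and t-SNE feature visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    signal,
    RNifti,
    xgboost,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
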