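Package: memdecode
Title: Decoding Individual Memories from Longitudinal fMRI Multivoxel Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multivoxel pattern analysis (MVPA) of
    slow event-related fMRI memory-recall experiments: trial-wise BOLD
    pattern extraction (smoothing, per-session linear detrending, canonical
    HRF convolution, onset shifting), ROI-restricted searchlight feature
    selection, error-correcting-output-codes multi-class linear SVM decoding
    with Hamming-distance recombination, information-map construction with
    Dice-overlap permutation testing, and group-level statistics (one-tailed
    tests against chance, paired tests, repeated-measures ANOVA). Includes a
    synthetic-data module that generates complete two-study experiments with
    planted per-memory voxel patterns, so every stage is testable without
    scanner data, plus minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
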