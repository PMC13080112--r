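Package: mstatefusion
Title: Multi-Paradigm EEG Microstate Analysis and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for EEG microstate analysis across resting-state and
    task paradigms: global field power (GFP) peak detection,
    polarity-invariant modified k-means segmentation into the canonical
    A-D topographies, backfitting without temporal smoothing, extraction
    of 26 per-segment microstate features (mean duration, coverage,
    occurrence, transition probabilities, global explained variance and
    Lempel-Ziv complexity), assumption-dispatched two-sample screening
    with Benjamini-Hochberg correction, mRMR feature ranking, and
    subject-grouped stratified repeated cross-validation of nested
    grid-searched support vector machines with resting/task/covariate
    fusion. Includes a semi-Markov synthetic EEG generator with known
    microstate ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    car,
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
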