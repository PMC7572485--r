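Package: EEGmicrostates
Title: EEG Microstate Segmentation, Lempel-Ziv Complexity and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for resting-state EEG microstate analysis: polarity-invariant
    modified k-means clustering of scalp topographies at global field power
    peaks, Krzanowski-Lai selection of the number of microstate classes,
    cohort-level map aggregation and alignment, backfitting of label
    sequences, microstate syntax statistics (duration, coverage, transition
    matrices) with the associated group tests (two-way ANOVA, Mann-Whitney U
    with normal-approximation z-scores, permutation TANOVA), Lempel-Ziv (LZ76)
    complexity of microstate transition sequences alongside classical
    Omega-complexity and binarized time-series LZC, theta relative power, and
    a two-feature support vector machine classifier with stratified
    cross-validation. Includes a semi-Markov synthetic EEG generator with
    known ground-truth topographies so every stage of the pipeline can be
    validated without clinical data, plus EDF and delimited-text I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    car,
    jsonlite,
    yaml,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
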