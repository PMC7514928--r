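Package: rankfuse
Title: Exact Consensus Combination of Rank Classifier Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines the outputs of an ensemble of rank classifiers into a
    single consensus ranking by solving the underlying binary linear programs
    exactly: a linear assignment problem under the disagreement (Hamming)
    distance and a linear ordering (Kemeny/Condorcet) problem under the
    Condorcet (Kendall tau) distance.  Provides conjunction coefficients that
    quantify ensemble agreement with their attainable intervals, a per-sample
    classification pipeline with error-rate / false-positive-rate /
    false-negative-rate evaluation for imbalanced problems, confusion-matrix
    rank-likelihood diagnostics, and a Mallows-model simulator of weak,
    possibly dependent, rank classifiers for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
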