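Package: stmf
Title: Sparse Tropical Matrix Factorization for Matrix Completion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Low-rank factorization of real matrices with missing entries over
    the tropical (max,+) semiring, used to impute missing values in gene
    expression and other sparse data. Provides the tropical matrix algebra
    (semiring addition and multiplication, the tropical partial order, the
    b-norm objective, greatest subsolutions of one-sided max-plus linear
    systems, and a masked (min,+) product that skips unknown entries), the
    sparse tropical matrix factorization (STMF) fitting algorithm with
    monotone-descent update rules and Random Acol initialization, a synthetic
    tropical low-rank data generator with uniform and structured masking,
    evaluation statistics (distance correlation via double centering, masked
    RMSE, centered per-row Euclidean errors) with a classical NMF baseline
    harness, delimited-matrix input/output with missing-value dialects, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
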