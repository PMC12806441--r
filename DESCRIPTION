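Package: tcrbind
Title: Transfer Learning and Ensemble Prediction of TCR-Peptide Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts binding between T cell receptor CDR3beta sequences and
    peptide epitopes with trainable recurrent and convolutional sequence-pair
    scorers, parameter transfer from a data-rich source task (CD8-like, ~9-mer
    peptides) to a scarce target task (CD4-like, ~15-mer peptides), ensemble
    score averaging, percentile binding ranks against a background TCR
    repertoire, edit-distance repertoire search, and a synthetic motif-based
    task generator that provides exact ground truth for validating every
    mechanism at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
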