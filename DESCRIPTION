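Package: tailanchor
Title: Hidden Markov Model Prediction of Tail-Anchored Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies amino-acid sequences as tail-anchored (TA) membrane
    proteins, which carry a single C-terminal transmembrane domain and no
    N-terminal signal sequence. Three region-structured hidden Markov models
    (a TA model read from the C-terminus, a signal-peptide single-pass model,
    and a signal-peptide multi-pass model) are trained by Baum-Welch and
    compared through length-normalised log-likelihood scores and through the
    Viterbi-decoded region structure (transmembrane-domain and tail lengths).
    Includes generators for labelled synthetic datasets with known region
    annotations, cross-validated scoring, balanced-error-rate threshold
    selection, ROC/AUC evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
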