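Package: persent
Title: Lexicon-Based Opinion Mining for Persian Patient Feedback
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mining opinions from short free-text patient feedback
    written in Persian. Provides rule-based orthographic normalization
    (character unification, half-space and affix standardization, kashida
    removal, spelling-variant mapping), a -5..+5 term-strength sentiment
    lexicon with rule-based negation shifters, sentence- and document-level
    polarity scoring with weighted aggregation, latent Dirichlet allocation
    fitted by collapsed Gibbs sampling with coherence-based topic-number
    selection, per-topic sentiment linkage, a binary-classification
    evaluation protocol (confusion matrix, precision, recall, specificity,
    accuracy, F-measure, AUC), and a synthetic corpus generator with known
    ground truth for end-to-end testing.
License: GPL-3
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
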