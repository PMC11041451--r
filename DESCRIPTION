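Package: ggonlp
Title: Extraction and Longitudinal Analysis of Ground-Glass Opacity Findings from Radiology Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deep-learning clinical natural language processing pipeline for
    ground-glass opacity (GGO) findings in free-text radiology notes. Provides a
    machine-readable GGO annotation ontology (15 entity types, 7 relation types),
    a synthetic radiology-note corpus generator with gold standoff annotations
    and known patient-level trajectories, readers and writers for BRAT standoff
    and JSONL corpora, bigram-aware word2vec query expansion, a Bi-LSTM tagger
    with a linear-chain conditional random field output layer (exact forward
    log-likelihood, Viterbi decoding, BIO span decoding, rule-based relation
    linking), entity normalization to structured GGO finding records (size in
    millimetres with clinical size bins, two-level anatomic location, etiology
    triage, status and temporal normalization), precision/recall/F1 scoring of
    predicted annotations against gold standards, and patient-level longitudinal
    trajectory analytics (persistence, size change, status change, pre-diagnosis
    intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
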