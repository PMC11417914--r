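Package: deamidr
Title: Sequence-Based Prediction of Antibody Deamidation Hot Spots
Version: 0.1.0
Authors@R:
    person("deamidr", "developers", email = "deamidr@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting asparagine and glutamine deamidation
    liabilities in therapeutic antibodies from sequence alone. Curates
    site-specific deamidation time courses from forced-degradation
    peptide-mapping experiments into hot-spot labels, encodes candidate
    sites by combining per-residue protein-language-model embeddings with
    a learned local-window recurrent encoder, trains a chimeric neural
    classifier (plus a three-timepoint extent-regression head), and
    evaluates with an imbalance-aware metric suite (MCC, ROC/AUC),
    stratified cross-validation, a window-size sweep and a canonical
    NG/NS/NN motif baseline. Includes a kinetics-based synthetic dataset
    generator and a deterministic mock embedder so the full workflow is
    testable without proprietary data or pretrained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
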