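Package: tcrbinder
Title: BERT-Style Transfer Learning for TCR-pMHC Binding Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scale-configurable framework for predicting T cell receptor (TCR)
    recognition of peptide-MHC (pMHC) complexes. Two transformer encoders are
    pretrained on CDR3-beta repertoires (masked language modelling) and on
    epitope-MHC presentation data (selective masking plus a binding-score
    regression head); a contrastive prediction head over the frozen encoder
    embeddings scores TCR-pMHC pairs and reports percentile ranks against a
    healthy background repertoire. Includes zero-shot benchmark utilities
    (AUC-ROC, AUC-PR, PPV at k, Youden cutoff, resampled negatives),
    attention-based residue-importance analytics, and seeded synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    bio3d,
    withr,
    Biostrings
Config/testthat/edition: 3
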