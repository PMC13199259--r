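Package: plectabm
Title: Piecewise Linear Encoding with Parameter-Efficient MLP Ensembles for
    Cardiotocography Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies fetal cardiotocography (CTG) feature tables — and
    generic three-class numeric tabular data — with a deep ensemble that shares
    one weight matrix across k multilayer-perceptron members, individualised by
    multiplicative adapter vectors, on top of a piecewise linear encoding of
    every numeric feature into learnable per-bin embeddings.  Ships the full
    surrounding pipeline: CSV ingestion and label recoding, seeded
    train/validation/test splitting, training-set standardisation, SMOTE
    minority oversampling, early-stopped Adam training, multiclass evaluation
    (per-class and macro precision/recall/F1, balanced accuracy), Gradient SHAP
    feature attribution with per-class rankings and pairwise interaction
    tables, and a synthetic CTG-like data generator with planted informative
    features for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
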