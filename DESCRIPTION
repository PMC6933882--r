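Package: sippred
Title: Self-Interacting Protein Prediction from PSSM Features with a
    Random-Projection Ensemble
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts self-interacting proteins (SIPs) from sequence profiles.
    Each protein's position-specific scoring matrix (PSSM) is smoothed with a
    window-method finite impulse response (FIR) filter along the sequence, the
    Gram matrix of the filtered amino-acid columns is flattened into a fixed
    400-dimensional feature vector, principal component analysis reduces the
    features to 300 dimensions, and a random-projection ensemble of
    leave-one-out-selected k-nearest-neighbour classifiers with a
    prior-probability voting threshold performs the highly imbalanced SIP /
    non-SIP classification. Includes PSI-BLAST ASCII PSSM input/output,
    dataset-curation predicates, a synthetic PSSM data generator, stratified
    cross-validation with confusion-matrix metrics (accuracy, sensitivity,
    specificity, precision, Matthews correlation coefficient) and ROC/AUC, and
    an optional RBF-SVM baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071
Suggests:
    Biostrings,
    pROC,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
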