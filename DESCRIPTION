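Package: glycLSTM
Title: LSTM Classification of Lysine Glycation Sites from Physicochemical
    Sequence Encodings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts nonenzymatic lysine glycation from protein sequence
    context. Encodes 31-residue lysine-centered peptide windows with eight
    physicochemical amino-acid scales (sequence order, hydropathy, mass,
    hydrophobicity, polarizability, van der Waals volume, backbone torsion
    preference, isoelectric point), trains a compact two-layer LSTM
    classifier with early stopping, and runs comparative experiment designs
    over single properties, all 28 property pairs, and the full eight-scale
    encoding, evaluated by accuracy, precision, sensitivity, specificity,
    Matthews correlation and ROC/AUC under repeat-averaged stratified
    splits and k-fold cross-validation. Includes a synthetic peptide
    generator with property-linked planted signal for end-to-end
    verification, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
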