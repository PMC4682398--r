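Package: neddly
Title: Prediction of Protein Neddylation Sites from Sequence-Derived Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting neddylation sites (covalent attachment of
    the ubiquitin-like modifier NEDD8 to substrate lysines) from protein
    sequences and sequence-derived structural properties. Provides
    lysine-centred window extraction with redundancy filtering and
    reproducible train/validation/test partitioning; featurization from
    sequence (one-hot, reduced-alphabet, composition), evolutionary
    conservation profiles (PSI-BLAST ASCII PSSM), secondary structure
    (PSIPRED .ss2), intrinsic disorder (IUPred), conformational flexibility
    (FlexPred) and solvent accessibility (WESA) predictor outputs;
    minimum-redundancy-maximum-relevance feature ordering with incremental
    feature selection; class-weighted radial-kernel support vector machine
    training with decision-value confidence thresholds; stratified
    cross-validation, ROC/AUC and confusion-matrix metrics; degenerate motif
    baselines; per-position residue enrichment statistics; and a
    deterministic synthetic benchmark generator with plantable signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
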