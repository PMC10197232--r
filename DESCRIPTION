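Package: mova
Title: Missense Variant Pathogenicity Scoring from AlphaFold Structural Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Per-gene machine-learning scoring of missense variant
    pathogenicity from the variant residue's position in the AlphaFold2
    predicted structure (mean atomic x/y/z coordinates), the pLDDT model
    confidence, and a BLOSUM62 substitution penalty. Implements random-forest
    training with repeated stratified five-fold cross-validation, rank-based
    ROC/AUC with vertically averaged ROC curves, Youden-index cutoffs, a
    minimum-distance-to-known-pathogenic-variant baseline, per-feature
    ablation, a 30-run ensemble scoring of every possible substitution of a
    protein, logistic-regression fusion with external scores such as REVEL or
    CADD, and a fully synthetic fixture generator (AlphaFold-style PDB chains
    with hotspot-clustered labeled variants) so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    bio3d,
    Biostrings,
    yaml
Config/testthat/edition: 3
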