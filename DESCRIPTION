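Package: tmvarboost
Title: Structure-Aware Classification of Missense Variants in Transmembrane Protein Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates disease-associated from benign point mutations in the
    transmembrane regions of proteins with known 3D structure. Builds all-atom
    mutant models by side-chain replacement followed by seeded Monte-Carlo
    repacking of the 5 Angstrom neighbourhood, computes a 96-component
    descriptor (28 sequence-, 44 structure-, and 24 energy-based features,
    including Shrake-Rupley solvent accessibility, Kabsch-Sander secondary
    structure, contact profiles and a native residue energy model), and trains
    a native second-order gradient-boosted decision-tree classifier that
    retains per-split gradient and Hessian statistics so regularised feature
    gain is computable exactly. Includes the evaluation protocols: class
    weighting for imbalanced data, z-normalisation, repeated k-fold
    cross-validation with paired t-statistic model selection, gain-based
    feature selection, leave-one-protein-out validation and in-silico
    saturation mutagenesis scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
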