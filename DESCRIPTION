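Package: hspred
Title: Hot Spot Residue Prediction at Protein-Protein Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Structure-based prediction of hot spot residues at
    protein-protein interfaces by computational alanine scanning.
    Per-residue molecular-mechanics energy features (van der Waals,
    hydrogen bond, Coulomb and desolvation terms over three structural
    regions of the complex) are scored by linear support vector
    machines, with specialist classifiers for arginine and glutamic
    acid mutations selected by a constrained feature-subset search
    inside a homology-cluster-aware nested cross-validation. Includes
    a synthetic-data module generating toy complexes and feature
    tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    e1071,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
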