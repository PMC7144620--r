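Package: pocketrank
Title: Ligand-Aware Rescoring and Ranking of Protein Binding-Pocket Decoys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rescores and ranks candidate ligand-binding pockets for a protein
    given its ligand. Ligands and pockets are represented as sums of learned
    substructure embeddings (a mol2vec-style featurization over Morgan circular
    substructure identifiers); the 600-dimensional concatenation of the ligand
    and pocket vectors is classified by a densely connected feed-forward neural
    network whose sigmoid output is the native-like probability used for
    ranking. Includes the decoy-labeling protocol (near-native by C-alpha
    centroid distance, negatives by distance plus a cosine-similarity filter),
    fixed and self normalization, a binary-classification metric suite
    (AUC, accuracy, TPR, precision, specificity, MCC), readers for PDB
    structures and fpocket-style pocket directories, a word2vec-text embedding
    table reader and writer, and synthetic generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
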