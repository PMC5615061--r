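Package: ogtscreen
Title: Ensemble-Docking Virtual Screening and Enzyme-Assay Analysis for
    OGT Inhibitor Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of a structure-ensemble virtual
    screening protocol for inhibitors of O-GlcNAc transferase (OGT):
    a physicochemical filter cascade (molecular weight, ionization,
    ring systems, hydrogen-bond donors/acceptors) over SMILES/SDF
    libraries, consensus re-ranking of AutoDock-Vina-style docking
    scores over a 16-member crystal-structure ensemble, Kabsch
    superposition and pose-RMSD clustering with biggest-cluster
    selection, geometric hydrogen-bond fingerprints with key-residue
    triage and a pairwise Coulomb/Lennard-Jones per-residue energy
    decomposition, plus analysis of enzyme assay readouts
    (four-parameter-logistic IC50 fitting and Cheng-Prusoff
    inhibition-mode prediction). Seeded synthetic-data generators
    provide compound libraries, score matrices, toy binding pockets
    and plate-reader data with ground truth known by construction, so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
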