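Package: cyclopep
Title: Cyclic Peptide Conformer Generation and Docking Preparation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds all-atom linear peptide conformers from sequence,
    closes head-to-tail and disulfide macrocycles by restrained simulated
    annealing, clusters the resulting conformational ensembles by pairwise
    backbone RMSD, prepares protein receptors and restraint/configuration
    files for information-driven docking (ambiguous interaction restraints,
    multibody restraints, staged sampling protocols), and assesses docked
    models against a reference complex with CAPRI-style fraction-of-native
    contacts and interface-RMSD quality criteria and top-N success rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
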