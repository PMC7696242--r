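Package: tripfib
Title: Conformational Fingerprinting and Packing Analysis of Self-Assembling Tripeptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for self-assembly ensembles of capped Phe/Ile
    tripeptides. Classifies backbone conformations into per-residue
    Ramachandran rotamer states and three-letter conformation codes,
    computes sidechain rotation-angle order parameters and the five-way
    syn/anti topology taxonomy, counts noncovalent interactions (sidechain
    contacts, solvent exposure, geometric hydrogen bonds) with a fiber-core
    filter, detects aggregates, filaments and their stacking rise, and
    matches sampled conformers to reference structures by minimum Kabsch
    RMSD. Includes an internal-coordinate structure builder that generates
    synthetic monomer ensembles, in-register filaments, multi-filament
    bundles and coarse solvent shells for testing and benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
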