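Package: cagekit
Title: Desk-Scale Characterization of Hollow Protein Cage Assemblies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structural characterization of hollow, homo-oligomeric protein
    cage assemblies at the desk scale. Provides predicted-aligned-error (PAE)
    based segmentation of protein chains into possibly non-contiguous
    structural domains, validation of cross-linking mass-spectrometry
    distance restraints on homo-oligomeric models with intra/inter-chain
    assignment, voxel-based detection of enclosed cavities with ellipsoid
    metrics, opening enumeration and interior/exterior surface-residue
    classification, size-exclusion chromatography calibration with
    oligomeric copy-number inference, Grishin protein distances with
    neighbor-joining trees, and seeded synthetic-data generators that ship
    machine-readable ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    bio3d,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
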