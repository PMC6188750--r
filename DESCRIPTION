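Package: pepterface
Title: Characterization of Protein-Peptide Interfaces from Docked Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for post-processing large-scale protein-peptide
    docking studies of small-ORF-encoded stress-induced peptides. Builds
    sliding-window k-mer fragment libraries with Kyte-Doolittle hydropathy
    descriptors, applies Benjamini-Hochberg screening statistics to
    binding-site predictions, constructs idealized peptide backbones from
    canonical dihedral angles, detects close contacts, hydrogen bonds,
    hydrophobic contacts, salt bridges and pi-pi stacks in docked complexes
    with explicit geometric criteria, tests pocket overlap with subunit
    interfaces and annotated ligand or catalytic sites, aggregates MM/GBSA
    snapshot energies into binding free energies with per-residue
    contribution analysis, and summarizes interaction statistics across
    cohorts of complexes. Synthetic-data generators with planted ground
    truth support end-to-end validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
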