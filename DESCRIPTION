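Package: hlagroove
Title: Pocket Assignment and Interaction Analysis of Drug Poses in the
    HLA Class I Peptide-Binding Groove
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how small-molecule drugs dock into the
    peptide-binding groove of HLA class I molecules, motivated by
    anti-thyroid-drug induced agranulocytosis associated with HLA-B
    alleles. Reads protein structures (PDB and the AutoDock PDBQT
    dialect) and multi-model docking pose sets with scores; selects
    non-associated control alleles from case/control/healthy allele
    frequency tables; scans multiple sequence alignments for residues
    unique to risk alleles; assigns docked poses to the B or F groove
    pocket (or outside the groove) by deterministic k-means on a
    reference atom; detects ligand-residue hydrophobic contacts and
    hydrogen bonds and classifies poses by their Thr80/thiocarbonyl
    interactions; summarises pose sets per allele, drug and search
    space; clusters allele peptide-binding score matrices into UPGMA
    trees; and generates fully seeded synthetic inputs with planted
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
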