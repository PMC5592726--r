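Package: gpcrcontacts
Title: Contact-Based Evaluation of Chemosensory GPCR-Agonist Structural Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate receptor-ligand structural models of
    chemosensory G-protein coupled receptors (bitter taste and odorant
    receptors) against site-directed mutagenesis data.  Detects
    protein-ligand contacts with a distance threshold plus a chemical
    interaction filter (hydrogen bonds, salt bridges, aromatic stacking,
    hydrophobic contacts), assigns GPCRdb-style generic residue numbers from
    an alignment to an annotated template, computes precision, recall and
    predictive power of predicted binding residues restricted to the
    extracellular half of the helix bundle, builds side-chain contact maps
    under a van der Waals sum criterion and compares them across
    active/inactive state pairs to find activation-related contact rewiring,
    and measures residue conservation and motif content in family
    alignments.  Ships seeded synthetic-data generators (idealized
    seven-helix bundles with planted contacts, mutagenesis tables with
    planted confusion matrices, family alignments with planted column
    frequencies, state pairs with planted rewired contacts) so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stringr,
    yaml,
    jsonlite,
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
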