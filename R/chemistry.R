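# Side-chain chemistry templates for the 20 standard amino acids.
# These drive the deterministic interaction-typing rules: which side-chain
# N/O atoms can donate/accept hydrogen bonds, which atoms carry formal
# charge at physiological pH, which atoms form aromatic rings, and which
# side-chain carbons count as apolar (not bonded to N or O in the residue
# topology).  Backbone N/O are deliberately absent: the chemical filter for
# ligand contacts considers side-chain functional groups only.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

sidechain_donors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), TRP = "NE1"
)

sidechain_acceptors <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), MET = "SD"
)

# formal charge carriers; His only when explicitly flagged protonated
sidechain_charges <- list(
  LYS = list(atoms = "NZ", charge = 1L),
  ARG = list(atoms = c("NE", "NH1", "NH2"), charge = 1L),
  ASP = list(atoms = c("OD1", "OD2"), charge = -1L),
  GLU = list(atoms = c("OE1", "OE2"), charge = -1L),
  HIS = list(atoms = c("ND1", "NE2"), charge = 1L)
)

sidechain_rings <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# side-chain carbons not bonded to N or O in the residue topology
sidechain_apolar_carbons <- list(
  ALA = "CB",
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  PRO = c("CB", "CG"),
  THR = "CG2",
  CYS = "CB",
  LYS = c("CB", "CG", "CD"),
  ARG = c("CB", "CG"),
  ASP = "CB",
  GLU = c("CB", "CG"),
  ASN = "CB",
  GLN = c("CB", "CG"),
  HIS = "CB"
)

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA1_TO_3 <- setNames(names(AA3_TO_1), unname(AA3_TO_1))

#' Construct a ligand chemistry descriptor
#'
#' Ligand chemistry is declared, never perceived from geometry: a descriptor
#' lists, per ligand atom name, the formal charge, aromatic-ring membership,
#' hydrogen-bond donor/acceptor capability and whether the atom is an apolar
#' carbon.  This mirrors the information a ligand-preparation tool would
#' output and avoids any bond-perception ambiguity.
#'
#' @param atom_name Character vector of ligand atom names.
#' @param charge Integer formal charges (0 for neutral atoms).
#' @param ring_id Integer aromatic-ring ids, `NA` for atoms in no ring.  Each
#'   ring id must group at least 5 atoms.
#' @param donor,acceptor Logical hydrogen-bond capability flags.
#' @param apolar Logical; `TRUE` marks an apolar carbon.
#' @return A tibble of class `ligand_descriptor`.
#' @examples
#' ligand_descriptor(
#'   atom_name = c("N1", "O1"),
#'   charge = c(1L, 0L),
#'   ring_id = c(NA, NA),
#'   donor = c(TRUE, FALSE),
#'   acceptor = c(FALSE, TRUE),
#'   apolar = c(FALSE, FALSE)
#' )
#' @export
ligand_descriptor <- function(atom_name, charge = 0L, ring_id = NA_integer_,
                              donor = FALSE, acceptor = FALSE,
                              apolar = FALSE) {
  d <- tibble(
    atom_name = as.character(atom_name),
    charge = as.integer(charge),
    ring_id = as.integer(ring_id),
    donor = as.logical(donor),
    acceptor = as.logical(acceptor),
    apolar = as.logical(apolar)
  )
  if (anyDuplicated(d$atom_name)) abort("duplicate ligand atom names in descriptor")
  ring_sizes <- table(d$ring_id[!is.na(d$ring_id)])
  if (any(ring_sizes < 5)) {
    abort("each aromatic ring id must group at least 5 atoms")
  }
  class(d) <- c("ligand_descriptor", class(d))
  d
}

#' Read a ligand chemistry descriptor from TSV
#'
#' Expects a header `atom_name charge ring_id donor acceptor apolar`;
#' `ring_id` may be empty/NA for non-ring atoms, flags are 0/1 or
#' TRUE/FALSE.
#'
#' @param path Path to the TSV file.
#' @return A `ligand_descriptor` tibble.
#' @export
read_ligand_descriptor <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    atom_name = readr::col_character(),
    charge = readr::col_integer(),
    ring_id = readr::col_integer(),
    donor = readr::col_logical(),
    acceptor = readr::col_logical(),
    apolar = readr::col_logical()
  ))
  do.call(ligand_descriptor, as.list(df))
}

#' Write a ligand chemistry descriptor to TSV
#' @param d A `ligand_descriptor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ligand_descriptor <- function(d, path) {
  readr::write_tsv(as_tibble(d), path)
  invisible(path)
}

# check that descriptor covers the ligand residue's heavy atoms and that
# apolar flags are only on carbons
validate_descriptor <- function(d, ligand_atoms) {
  missing <- setdiff(ligand_atoms$name, d$atom_name)
  if (length(missing)) {
    abort(paste0("ligand descriptor missing atoms: ",
                 paste(missing, collapse = ", ")))
  }
  ap <- d$atom_name[d$apolar]
  elems <- setNames(toupper(ligand_atoms$element), ligand_atoms$name)
  bad <- ap[elems[ap] != "C"]
  bad <- bad[!is.na(bad)]
  if (length(bad)) {
    abort(paste0("apolar flag on non-carbon ligand atoms: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(d)
}
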