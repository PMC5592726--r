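#' Structure models
#'
#' A `structure_model` holds one parsed 3-D structure as a flat atom table
#' plus an identifier and an activation-state label.  Atoms are partitioned
#' into polymer (ATOM records), hetero (HETATM, e.g. the ligand) and water;
#' polymer atoms are additionally split into backbone (N, CA, C, O, OXT) and
#' side chain.  All distance computations in the package ignore hydrogens.
#'
#' @name structure_model
#' @keywords internal
NULL

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3", "SOL")

res_key <- function(chain, seqnum, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  chain <- ifelse(is.na(chain), "_", chain)
  sprintf("%s:%d%s", chain, as.integer(seqnum), icode)
}

new_structure_model <- function(atoms, id = "structure",
                                state_label = "unspecified") {
  state_label <- match.arg(state_label, c("active", "inactive", "unspecified"))
  atoms <- as_tibble(atoms)
  needed <- c("serial", "name", "element", "x", "y", "z", "occupancy",
              "altloc", "chain", "seqnum", "icode", "resname", "record_class")
  missing <- setdiff(needed, names(atoms))
  if (length(missing)) {
    abort(paste0("atom table missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite atom coordinates")
  }
  blank <- is.na(atoms$element) | atoms$element == ""
  if (any(blank)) {
    atoms$element[blank] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                                atoms$name[blank]), 1L, 1L))
    warn(sprintf("%d atom(s) had no element symbol; used first character of atom name",
                 sum(blank)))
  }
  atoms$element <- toupper(atoms$element)
  atoms$res_key <- res_key(atoms$chain, atoms$seqnum, atoms$icode)
  atoms$is_backbone <- atoms$record_class == "polymer" &
    atoms$name %in% BACKBONE_ATOMS
  if (!any(atoms$record_class == "polymer")) {
    abort("structure contains no polymer residues")
  }
  dup <- atoms |>
    distinct(.data$res_key, .data$record_class) |>
    dplyr::count(.data$res_key) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("residue identity appears in multiple record classes: ",
                 paste(dup$res_key, collapse = ", ")))
  }
  structure(list(id = id, atoms = atoms, state_label = state_label),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  rs <- residues(x)
  cat(sprintf("<structure_model> %s (%s)\n", x$id, x$state_label))
  cat(sprintf("  %d polymer residues, %d ligand(s), %d atoms\n",
              sum(rs$record_class == "polymer"),
              sum(rs$record_class == "hetero"),
              nrow(x$atoms)))
  invisible(x)
}

#' Residue summary of a structure
#'
#' @param s A `structure_model`.
#' @return A tibble with one row per residue: `chain`, `seqnum`, `icode`,
#'   `resname`, `res_key`, `record_class`, `n_atoms`, in file order.
#' @export
residues <- function(s) {
  s$atoms |>
    group_by(.data$res_key) |>
    summarise(
      chain = .data$chain[1], seqnum = .data$seqnum[1], icode = .data$icode[1],
      resname = .data$resname[1], record_class = .data$record_class[1],
      n_atoms = n(), .groups = "drop"
    ) |>
    arrange(match(.data$res_key, unique(s$atoms$res_key))) |>
    select("chain", "seqnum", "icode", "resname", "res_key",
           "record_class", "n_atoms")
}

#' Ligand residues of a structure
#'
#' @param s A `structure_model`.
#' @return Residue summary rows for hetero (non-water) residues.
#' @export
ligands <- function(s) {
  filter(residues(s), .data$record_class == "hetero")
}

#' Atom rows of one residue
#'
#' @param s A `structure_model`.
#' @param key A residue key (`"chain:seqnum"`, e.g. `"A:12"`).
#' @return The atom tibble subset for that residue.
#' @export
residue_atoms <- function(s, key) {
  out <- filter(s$atoms, .data$res_key == key)
  if (!nrow(out)) abort(paste0("no residue with key ", key))
  out
}

# ---- parsing -------------------------------------------------------------

check_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  coord <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(coord)) abort("no ATOM/HETATM records found")
  for (i in coord) {
    xyz <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
             substr(lines[i], 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(xyz))))) {
      abort(sprintf("malformed coordinate field at line %d: %s", i, lines[i]))
    }
  }
  invisible(coord)
}

#' Read a structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records (via bio3d), classifies atoms as
#' polymer, hetero or water, and resolves alternate locations.  Under the
#' default policy only the highest-occupancy conformer of each atom is kept
#' (ties resolved alphabetically by altloc, so conformer A wins).
#'
#' @param path Path to a PDB file.
#' @param id Structure identifier; defaults to the file name.
#' @param state_label Activation state: `"active"`, `"inactive"` or
#'   `"unspecified"`.
#' @param altloc_policy `"highest_occupancy"` (default) or `"first"`.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, id = NULL,
                           state_label = "unspecified",
                           altloc_policy = c("highest_occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  lines <- readLines(path, warn = FALSE)
  check_pdb_lines(lines)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  a <- pdb$atom
  atoms <- tibble(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    element = toupper(trimws(ifelse(is.na(a$elesy), "", a$elesy))),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    chain = ifelse(is.na(a$chain), "A", a$chain),
    seqnum = as.integer(a$resno),
    icode = ifelse(is.na(a$insert), "", a$insert),
    resname = trimws(a$resid),
    record_class = dplyr::case_when(
      trimws(a$resid) %in% WATER_NAMES ~ "water",
      a$type == "HETATM" ~ "hetero",
      TRUE ~ "polymer"
    )
  )
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1)) {
    abort("occupancy outside [0, 1]")
  }
  atoms <- resolve_altloc(atoms, altloc_policy)
  new_structure_model(atoms,
                      id = id %||% sub("\\.pdb$", "", basename(path)),
                      state_label = state_label)
}

#' Parse a structure from PDB text
#'
#' @param text Character vector of PDB lines (or a single string with
#'   embedded newlines).
#' @inheritParams read_structure
#' @return A `structure_model`.
#' @export
parse_structure <- function(text, id = "structure",
                            state_label = "unspecified",
                            altloc_policy = c("highest_occupancy", "first")) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(text, tmp)
  read_structure(tmp, id = id, state_label = state_label,
                 altloc_policy = match.arg(altloc_policy))
}

resolve_altloc <- function(atoms, policy) {
  atoms |>
    group_by(.data$chain, .data$seqnum, .data$icode, .data$name) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) == 1L) return(df)
      if (policy == "highest_occupancy") {
        df <- df[order(-df$occupancy, df$altloc), , drop = FALSE]
      }
      df[1L, , drop = FALSE]
    }) |>
    ungroup() |>
    arrange(.data$serial)
}

# ---- writing -------------------------------------------------------------

format_pdb_atom <- function(record, serial, name, resname, chain, seqnum,
                            icode, x, y, z, occupancy, element) {
  name_f <- ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name))
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_f, "", resname, chain, seqnum,
          ifelse(icode == "", " ", icode), x, y, z, occupancy, 0,
          toupper(element))
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM/HETATM records (and a final END) that round-trip
#' through [read_structure()] with coordinates preserved to the format's
#' 1e-3 Angstrom precision.
#'
#' @param s A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  writeLines(structure_to_pdb(s), path)
  invisible(path)
}

#' Render a structure as PDB text lines
#' @param s A `structure_model`.
#' @return Character vector of PDB lines.
#' @export
structure_to_pdb <- function(s) {
  a <- s$atoms
  rec <- ifelse(a$record_class == "polymer", "ATOM", "HETATM")
  lines <- format_pdb_atom(rec, a$serial, a$name, a$resname, a$chain,
                           a$seqnum, a$icode, a$x, a$y, a$z, a$occupancy,
                           a$element)
  c(lines, "END")
}

# ---- geometry ------------------------------------------------------------

coords_matrix <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

# min cross distance between two coordinate matrices
cross_min_dist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  sqrt(max(0, min(d2)))
}

drop_hydrogens <- function(atoms) filter(atoms, .data$element != "H")

#' Minimum heavy-atom distance between two residues
#'
#' Returns the minimum pairwise Euclidean distance over non-hydrogen atoms,
#' optionally restricted to side-chain atoms.  A residue with no atoms
#' surviving the filter (e.g. glycine under `sidechain_only`) raises a
#' classed `gpcr_empty_selection` error, so an empty selection is always
#' distinguishable from a large distance.
#'
#' @param a,b Atom tibbles for the two residues (see [residue_atoms()]).
#' @param atom_filter `"all"` or `"sidechain_only"`.
#' @return Distance in Angstrom.
#' @export
min_residue_distance <- function(a, b, atom_filter = c("all", "sidechain_only")) {
  atom_filter <- match.arg(atom_filter)
  a <- drop_hydrogens(a)
  b <- drop_hydrogens(b)
  if (atom_filter == "sidechain_only") {
    a <- filter(a, !.data$is_backbone)
    b <- filter(b, !.data$is_backbone)
  }
  if (!nrow(a) || !nrow(b)) {
    abort("no atoms survive the filter", class = "gpcr_empty_selection")
  }
  cross_min_dist(coords_matrix(a), coords_matrix(b))
}

#' Principal axis of a transmembrane helix bundle
#'
#' The axis is the first principal direction of the C-alpha coordinates of
#' the supplied transmembrane residues, oriented so that the most
#' N-terminal residue of the set projects positively (class A topology:
#' extracellular N-terminus, so the positive direction points to the
#' extracellular "top" half).
#'
#' @param s A `structure_model`.
#' @param tm_residues Character vector of residue keys defining the TM
#'   bundle; defaults to all polymer residues.
#' @return A list with unit 3-vector `axis` and 3-vector `centroid`.
#' @export
bundle_axis <- function(s, tm_residues = NULL) {
  rs <- residues(s)
  keys <- tm_residues %||% rs$res_key[rs$record_class == "polymer"]
  ca <- filter(s$atoms, .data$res_key %in% keys, .data$name == "CA")
  if (nrow(ca) < 3) abort("need at least 3 C-alpha atoms to define an axis")
  X <- coords_matrix(ca)
  centroid <- colMeans(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] < 1e-9) abort("degenerate C-alpha coordinates (all coincident)")
  axis <- pc$rotation[, 1]
  # orient: the most N-terminal residue of the TM set projects positively
  ord <- order(match(ca$res_key, unique(s$atoms$res_key)))
  first_ca <- X[ord[1], ]
  if (sum((first_ca - centroid) * axis) < 0) axis <- -axis
  list(axis = unname(axis / sqrt(sum(axis^2))), centroid = unname(centroid))
}
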