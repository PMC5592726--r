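#' Detect receptor-ligand contacts
#'
#' A polymer residue is in atomic contact with the ligand when the minimum
#' heavy-atom distance between them is below the contact cutoff (5.5
#' Angstrom by default, the sum of two carbon van der Waals radii plus a
#' water-molecule diameter).  Each contact is then typed by
#' [classify_interaction()]; a contact "passes the chemical filter" when at
#' least one classical interaction label (hydrogen bond, salt bridge,
#' aromatic stacking, hydrophobic) applies.
#'
#' @param s A `structure_model`.
#' @param ligand_key Residue key of the ligand (a hetero residue of `s`);
#'   defaults to the first ligand.
#' @param descriptor A [ligand_descriptor()] covering the ligand's heavy
#'   atoms.
#' @param thresholds A [contact_thresholds()].
#' @param map Optional `numbering_map`; when given, contacts are annotated
#'   with generic positions.
#' @param his_protonated Treat histidine as positively charged (default
#'   `FALSE`: neutral donor/acceptor).
#' @return A tibble of class `ligand_contacts`, one row per contacting
#'   residue ordered by (chain, seqnum): `res_key`, `chain`, `seqnum`,
#'   `resname`, `generic`, `min_dist`, `labels` (comma-joined),
#'   `passes_chemical_filter`.
#' @export
detect_ligand_contacts <- function(s, ligand_key = NULL, descriptor,
                                   thresholds = contact_thresholds(),
                                   map = NULL, his_protonated = FALSE) {
  t <- as_contact_thresholds(thresholds)
  lig <- ligands(s)
  if (!nrow(lig)) abort("structure has no ligand (hetero) residues")
  ligand_key <- ligand_key %||% lig$res_key[1]
  if (!ligand_key %in% lig$res_key) {
    abort(paste0(ligand_key, " is not a ligand residue of the structure"))
  }
  lat <- drop_hydrogens(residue_atoms(s, ligand_key))
  validate_descriptor(descriptor, lat)

  pat <- drop_hydrogens(filter(s$atoms, .data$record_class == "polymer"))
  L <- coords_matrix(lat)
  P <- coords_matrix(pat)
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * tcrossprod(P, L)
  dmin_atom <- sqrt(pmax(0, apply(d2, 1, min)))
  per_res <- tibble(res_key = pat$res_key, d = dmin_atom) |>
    group_by(.data$res_key) |>
    summarise(min_dist = min(.data$d), .groups = "drop") |>
    filter(.data$min_dist < t$ligand_contact_cutoff)

  rs <- residues(s)
  out <- per_res |>
    left_join(rs, by = "res_key") |>
    arrange(.data$chain, .data$seqnum)
  labels <- purrr::map(out$res_key, function(k) {
    classify_interaction(residue_atoms(s, k), lat, descriptor, t,
                         his_protonated = his_protonated)
  })
  passes <- lengths(labels) > 0
  out <- out |>
    mutate(
      generic = if (is.null(map)) NA_character_ else generic_of(map, .data$res_key),
      labels = vapply(labels, paste, character(1), collapse = ","),
      passes_chemical_filter = passes
    ) |>
    select("res_key", "chain", "seqnum", "resname", "generic", "min_dist",
           "labels", "passes_chemical_filter")
  class(out) <- c("ligand_contacts", class(out))
  attr(out, "structure_id") <- s$id
  attr(out, "ligand_key") <- ligand_key
  out
}

#' Classify the chemical interaction(s) between a residue and a ligand
#'
#' Deterministic geometric rules replace the visual inspection step of a
#' manual analysis:
#' \itemize{
#'   \item \emph{hbond}: a side-chain donor/acceptor N/O (or S) of the
#'     residue within `hbond_max` of a complementary ligand
#'     acceptor/donor atom;
#'   \item \emph{salt_bridge}: a charged side-chain group atom (Lys NZ, Arg
#'     NE/NH1/NH2, Asp OD1/OD2, Glu OE1/OE2, His ND1/NE2 when protonated)
#'     within `salt_bridge_max` of an oppositely charged ligand atom;
#'   \item \emph{aromatic_stacking}: the centroids of a residue ring
#'     (Phe/Tyr/Trp/His) and a ligand aromatic ring within
#'     `ring_centroid_max`;
#'   \item \emph{hydrophobic}: an apolar side-chain carbon (not bonded to
#'     N/O in the residue topology) within `hydrophobic_max` of an apolar
#'     ligand carbon.
#' }
#' Backbone atoms never contribute: polar proximity through the backbone
#' alone yields no label.
#'
#' @param r Atom tibble of the residue (see [residue_atoms()]).
#' @param ligand Atom tibble of the ligand residue.
#' @param descriptor A [ligand_descriptor()].
#' @param thresholds A [contact_thresholds()].
#' @param his_protonated Treat His as charged.
#' @return Character vector: subset of
#'   `c("hbond", "salt_bridge", "aromatic_stacking", "hydrophobic")`
#'   (empty when no rule applies, i.e. the contact fails the chemical
#'   filter).
#' @export
classify_interaction <- function(r, ligand, descriptor,
                                 thresholds = contact_thresholds(),
                                 his_protonated = FALSE) {
  t <- as_contact_thresholds(thresholds)
  r <- drop_hydrogens(r)
  ligand <- drop_hydrogens(ligand)
  resname <- r$resname[1]
  d <- descriptor
  labels <- character()

  sel <- function(atoms, names) filter(atoms, .data$name %in% names)
  within_d <- function(a, b, cutoff) {
    nrow(a) > 0 && nrow(b) > 0 &&
      cross_min_dist(coords_matrix(a), coords_matrix(b)) <= cutoff
  }

  # hydrogen bond: complementary donor/acceptor pairs
  r_don <- sel(r, sidechain_donors[[resname]])
  r_acc <- sel(r, sidechain_acceptors[[resname]])
  l_acc <- sel(ligand, d$atom_name[d$acceptor])
  l_don <- sel(ligand, d$atom_name[d$donor])
  if (within_d(r_don, l_acc, t$hbond_max) ||
      within_d(r_acc, l_don, t$hbond_max)) {
    labels <- c(labels, "hbond")
  }

  # salt bridge: opposite formal charges
  chg <- sidechain_charges[[resname]]
  if (!is.null(chg) && (resname != "HIS" || his_protonated)) {
    r_chg <- sel(r, chg$atoms)
    l_opp <- sel(ligand, d$atom_name[d$charge * chg$charge < 0])
    if (within_d(r_chg, l_opp, t$salt_bridge_max)) {
      labels <- c(labels, "salt_bridge")
    }
  }

  # aromatic stacking: ring centroid distance
  ring_atoms <- sel(r, sidechain_rings[[resname]])
  if (nrow(ring_atoms) >= 3) {
    r_cen <- colMeans(coords_matrix(ring_atoms))
    lig_rings <- unique(d$ring_id[!is.na(d$ring_id)])
    for (rid in lig_rings) {
      l_ring <- sel(ligand, d$atom_name[!is.na(d$ring_id) & d$ring_id == rid])
      if (nrow(l_ring) >= 3) {
        l_cen <- colMeans(coords_matrix(l_ring))
        if (sqrt(sum((r_cen - l_cen)^2)) <= t$ring_centroid_max) {
          labels <- c(labels, "aromatic_stacking")
          break
        }
      }
    }
  }

  # hydrophobic: apolar carbon pair
  r_ap <- sel(r, sidechain_apolar_carbons[[resname]])
  l_ap <- sel(ligand, d$atom_name[d$apolar])
  if (within_d(r_ap, l_ap, t$hydrophobic_max)) {
    labels <- c(labels, "hydrophobic")
  }

  labels
}

#' Build a side-chain residue-residue contact map
#'
#' A residue pair is in contact when some pair of side-chain heavy atoms
#' (backbone atoms excluded, so glycine participates in no pairs) lies
#' closer than the sum of the two atoms' van der Waals radii plus
#' `vdw_tolerance`, and the residues are at least `min_seq_separation`
#' apart in sequence (pairs on different chains always qualify).
#'
#' @param s A `structure_model`.
#' @param vdw A [vdw_table()].
#' @param thresholds A [contact_thresholds()].
#' @return A tibble of class `contact_map`: `res_key_i`, `res_key_j`
#'   (unordered pairs stored with i before j in file order), `chain_i`,
#'   `seqnum_i`, `chain_j`, `seqnum_j`, `min_dist` (minimum side-chain
#'   heavy-atom distance).
#' @export
build_contact_map <- function(s, vdw = vdw_table(),
                              thresholds = contact_thresholds()) {
  t <- as_contact_thresholds(thresholds)
  sc <- s$atoms |>
    filter(.data$record_class == "polymer", !.data$is_backbone,
           .data$element != "H")
  empty <- tibble(res_key_i = character(), res_key_j = character(),
                  chain_i = character(), seqnum_i = integer(),
                  chain_j = character(), seqnum_j = integer(),
                  min_dist = double())
  if (nrow(sc) < 2) return(as_contact_map(empty, s))

  X <- coords_matrix(sc)
  r <- vdw_radius(vdw, sc$element, sc$name)
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  D <- sqrt(pmax(d2, 0))
  cutoff <- outer(r, r, "+") + t$vdw_tolerance
  hit <- D < cutoff
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) return(as_contact_map(empty, s))

  pairs <- tibble(
    key_a = sc$res_key[idx[, 1]], key_b = sc$res_key[idx[, 2]],
    chain_a = sc$chain[idx[, 1]], chain_b = sc$chain[idx[, 2]],
    sn_a = sc$seqnum[idx[, 1]], sn_b = sc$seqnum[idx[, 2]],
    d = D[idx]
  ) |>
    filter(.data$key_a != .data$key_b) |>
    filter(.data$chain_a != .data$chain_b |
             abs(.data$sn_a - .data$sn_b) >= t$min_seq_separation)
  if (!nrow(pairs)) return(as_contact_map(empty, s))

  # canonical pair order: file order of residues in the structure
  ord <- match(pairs$key_a, unique(s$atoms$res_key)) >
    match(pairs$key_b, unique(s$atoms$res_key))
  swap <- function(a, b) list(ifelse(ord, b, a), ifelse(ord, a, b))
  k <- swap(pairs$key_a, pairs$key_b)
  ch <- swap(pairs$chain_a, pairs$chain_b)
  sn <- swap(pairs$sn_a, pairs$sn_b)
  out <- tibble(res_key_i = k[[1]], res_key_j = k[[2]],
                chain_i = ch[[1]], seqnum_i = as.integer(sn[[1]]),
                chain_j = ch[[2]], seqnum_j = as.integer(sn[[2]]),
                d = pairs$d) |>
    group_by(.data$res_key_i, .data$res_key_j, .data$chain_i,
             .data$seqnum_i, .data$chain_j, .data$seqnum_j) |>
    summarise(hit_dist = min(.data$d), .groups = "drop")
  # record the true minimum side-chain distance for each included pair
  out$min_dist <- purrr::map2_dbl(out$res_key_i, out$res_key_j, function(a, b) {
    min_residue_distance(residue_atoms(s, a), residue_atoms(s, b),
                         atom_filter = "sidechain_only")
  })
  out <- arrange(out, .data$chain_i, .data$seqnum_i, .data$chain_j,
                 .data$seqnum_j) |>
    select(-"hit_dist")
  as_contact_map(out, s)
}

as_contact_map <- function(df, s) {
  class(df) <- c("contact_map", class(df))
  attr(df, "structure_id") <- s$id
  attr(df, "state_label") <- s$state_label
  df
}

#' Write / read a contact map as an edge-list TSV
#' @param cm A `contact_map`.
#' @param path File path.
#' @return `path` (write) or a `contact_map`-shaped tibble (read).
#' @export
write_contact_map <- function(cm, path) {
  readr::write_tsv(as_tibble(cm), path)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    res_key_i = readr::col_character(), res_key_j = readr::col_character(),
    chain_i = readr::col_character(), seqnum_i = readr::col_integer(),
    chain_j = readr::col_character(), seqnum_j = readr::col_integer(),
    min_dist = readr::col_double()
  ))
  class(df) <- c("contact_map", class(df))
  df
}

# canonical generic-pair table: pos_a before pos_b in (helix, offset) order
canonical_generic_pairs <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  dropped <- sum(!ok)
  gi <- gi[ok]; gj <- gj[ok]
  if (length(gi)) {
    pi <- parse_generic(gi); pj <- parse_generic(gj)
    flip <- pi$helix > pj$helix | (pi$helix == pj$helix & pi$offset > pj$offset)
    a <- ifelse(flip, gj, gi)
    b <- ifelse(flip, gi, gj)
    out <- distinct(tibble(pos_a = a, pos_b = b))
  } else {
    out <- tibble(pos_a = character(), pos_b = character())
  }
  attr(out, "dropped") <- dropped
  out
}

#' Difference between two contact maps in generic-position space
#'
#' Translates each map's residue pairs into generic-position pairs via the
#' corresponding numbering map (pairs containing an unmapped residue are
#' dropped and counted), then reports which pairs are present only in the
#' active map (`gained`) or only in the inactive map (`lost`).  Swapping
#' the arguments swaps the two sets.
#'
#' @param active,inactive `contact_map` objects.
#' @param map_active,map_inactive `numbering_map` objects for the two
#'   structures.
#' @return A list with tibbles `gained` and `lost` (columns `pos_a`,
#'   `pos_b`, canonically ordered) and `dropped`, the per-map count of
#'   contact pairs lost to unmapped residues.
#' @export
diff_contact_maps <- function(active, inactive, map_active, map_inactive) {
  ga <- canonical_generic_pairs(generic_of(map_active, active$res_key_i),
                                generic_of(map_active, active$res_key_j))
  gi <- canonical_generic_pairs(generic_of(map_inactive, inactive$res_key_i),
                                generic_of(map_inactive, inactive$res_key_j))
  key <- function(df) paste(df$pos_a, df$pos_b, sep = "|")
  gained <- ga[!(key(ga) %in% key(gi)), ]
  lost <- gi[!(key(gi) %in% key(ga)), ]
  list(
    gained = as_tibble(gained),
    lost = as_tibble(lost),
    dropped = c(active = attr(ga, "dropped"), inactive = attr(gi, "dropped"))
  )
}

#' Write ligand contacts as TSV
#' @param contacts A `ligand_contacts` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  readr::write_tsv(as_tibble(contacts), path)
  invisible(path)
}
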