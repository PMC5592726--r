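#' Distance thresholds for contact detection and interaction typing
#'
#' Bundles every geometric cutoff used by the contact stages.  The
#' protein-ligand contact rule uses a single heavy-atom distance threshold
#' (5.5 Angstrom by default); individual chemical interaction types each have
#' their own, tighter cutoff.  Residue-residue contact maps use a van der
#' Waals radius-sum criterion with an additive tolerance.
#'
#' @param ligand_contact_cutoff Heavy-atom distance below which a
#'   protein-ligand atomic contact is counted, in Angstrom.
#' @param hbond_max Maximum donor/acceptor heavy-atom distance for a hydrogen
#'   bond, in Angstrom.
#' @param salt_bridge_max Maximum distance between oppositely charged group
#'   atoms for a salt bridge, in Angstrom.
#' @param ring_centroid_max Maximum ring centroid-centroid distance for
#'   aromatic stacking, in Angstrom.
#' @param hydrophobic_max Maximum apolar carbon-carbon distance for a
#'   hydrophobic contact, in Angstrom.
#' @param vdw_tolerance Additive tolerance on the van der Waals radius sum in
#'   the residue-residue contact rule, in Angstrom.  Set to 0 to recover the
#'   strict "shorter than the sum of the radii" rule.
#' @param min_seq_separation Minimum sequence separation (same chain) for a
#'   residue pair to enter a contact map.
#'
#' @return An object of class `contact_thresholds` (a named list).
#' @examples
#' contact_thresholds()
#' contact_thresholds(vdw_tolerance = 0)
#' @export
contact_thresholds <- function(ligand_contact_cutoff = 5.5,
                               hbond_max = 3.5,
                               salt_bridge_max = 4.0,
                               ring_centroid_max = 5.0,
                               hydrophobic_max = 4.5,
                               vdw_tolerance = 0.6,
                               min_seq_separation = 4L) {
  t <- list(
    ligand_contact_cutoff = ligand_contact_cutoff,
    hbond_max = hbond_max,
    salt_bridge_max = salt_bridge_max,
    ring_centroid_max = ring_centroid_max,
    hydrophobic_max = hydrophobic_max,
    vdw_tolerance = vdw_tolerance,
    min_seq_separation = as.integer(min_seq_separation)
  )
  dists <- t[c("ligand_contact_cutoff", "hbond_max", "salt_bridge_max",
               "ring_centroid_max", "hydrophobic_max")]
  if (any(vapply(dists, function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    abort("all distance thresholds must be positive numbers")
  }
  if (t$vdw_tolerance < 0) abort("`vdw_tolerance` must be >= 0")
  if (t$min_seq_separation < 0) abort("`min_seq_separation` must be >= 0")
  for (nm in c("hbond_max", "salt_bridge_max", "hydrophobic_max",
               "ring_centroid_max")) {
    if (t[[nm]] > t$ligand_contact_cutoff) {
      abort(sprintf("`%s` (%.2f) exceeds `ligand_contact_cutoff` (%.2f)",
                    nm, t[[nm]], t$ligand_contact_cutoff))
    }
  }
  structure(t, class = "contact_thresholds")
}

#' @export
print.contact_thresholds <- function(x, ...) {
  cat("<contact_thresholds>\n")
  for (nm in names(x)) {
    unit <- if (nm == "min_seq_separation") "residues" else "A"
    cat(sprintf("  %-22s %s %s\n", nm, format(x[[nm]]), unit))
  }
  invisible(x)
}

as_contact_thresholds <- function(x) {
  if (inherits(x, "contact_thresholds")) return(x)
  if (is.null(x)) return(contact_thresholds())
  do.call(contact_thresholds, as.list(x))
}
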