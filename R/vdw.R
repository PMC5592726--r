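#' Van der Waals radii
#'
#' A Bondi-style radius table used by the residue-residue contact criterion
#' (two side-chain heavy atoms are in contact when their distance is below
#' the sum of their radii plus a tolerance).  The default covers the elements
#' found in protein heavy atoms plus common hetero-atom elements; it can be
#' replaced wholesale from a two-column TSV via [read_vdw_table()].
#'
#' @return A named numeric vector of radii in Angstrom, class `vdw_table`.
#' @examples
#' vdw_table()[["C"]]
#' @export
vdw_table <- function() {
  new_vdw_table(c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
  ))
}

new_vdw_table <- function(radii) {
  radii <- unlist(radii)
  if (!is.numeric(radii) || is.null(names(radii))) {
    abort("a vdW table is a named numeric vector (element -> radius)")
  }
  names(radii) <- toupper(names(radii))
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    abort("all vdW radii must be finite and > 0")
  }
  required <- c("C", "N", "O", "S", "P", "H")
  missing <- setdiff(required, names(radii))
  if (length(missing)) {
    abort(paste0("vdW table must cover elements: ",
                 paste(missing, collapse = ", ")))
  }
  structure(radii, class = "vdw_table")
}

#' Read a van der Waals radius table from a two-column TSV
#'
#' The file has columns `element` and `radius` (Angstrom), with a header.
#'
#' @param path Path to the TSV file.
#' @return A `vdw_table`.
#' @export
read_vdw_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    element = readr::col_character(),
    radius = readr::col_double()
  ))
  new_vdw_table(setNames(df$radius, df$element))
}

# radius lookup with the documented fallback: unknown element -> first
# character of the atom name, with a warning
vdw_radius <- function(vdw, element, atom_name = element) {
  element <- toupper(element)
  r <- unname(vdw[element])
  miss <- is.na(r)
  if (any(miss)) {
    fallback <- toupper(substr(atom_name[miss], 1L, 1L))
    r[miss] <- unname(vdw[fallback])
    if (any(is.na(r))) {
      abort(paste0("no vdW radius for element(s): ",
                   paste(unique(element[is.na(r)]), collapse = ", ")))
    }
    warn(paste0("unknown element(s) ",
                paste(unique(element[miss]), collapse = ", "),
                "; fell back to first character of atom name"))
  }
  r
}
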