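#' Aligned receptor families
#'
#' An `aligned_family` couples a multiple sequence alignment with a
#' reference row and a [reference_annotation()], so alignment columns can
#' be addressed by generic position.  The column map is derived from the
#' reference row: a column maps to `h.oo` when the reference residue at
#' that column falls inside helix `h`'s transmembrane span, with offset
#' counted from the `X.50` anchor.
#'
#' @param ids Character vector of sequence ids.
#' @param seqs Character vector of aligned sequences (equal length, `-` for
#'   gaps).
#' @param ref_id Id of the reference (template) row.
#' @param annotation A [reference_annotation()].
#' @return An object of class `aligned_family`.
#' @export
aligned_family <- function(ids, seqs, ref_id, annotation) {
  if (length(ids) != length(seqs)) abort("ids and seqs differ in length")
  if (anyDuplicated(ids)) abort("duplicate sequence ids")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) abort("all alignment rows must have equal length")
  if (!ref_id %in% ids) abort("reference row not present in the alignment")

  ref <- strsplit(toupper(seqs[ids == ref_id]), "")[[1]]
  ref_pos <- ifelse(ref == "-", NA_integer_, cumsum(ref != "-"))
  spans <- annotation$spans
  cols <- list()
  for (h in seq_len(nrow(spans))) {
    sel <- which(!is.na(ref_pos) & ref_pos >= spans$start[h] &
                   ref_pos <= spans$end[h])
    if (!length(sel)) next
    off <- 50L + ref_pos[sel] - spans$anchor[h]
    ok <- off >= 1L & off <= 99L
    cols[[h]] <- tibble(column = sel[ok], helix = spans$helix[h],
                        offset = off[ok],
                        generic = generic_position(spans$helix[h], off[ok]))
  }
  column_map <- bind_rows(cols)
  if (anyDuplicated(column_map$generic)) {
    abort("column map is not injective on generic positions")
  }
  structure(list(
    rows = tibble(id = as.character(ids), seq = toupper(seqs)),
    ref_id = ref_id, annotation = annotation, column_map = column_map
  ), class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("<aligned_family> %d rows x %d columns, %d TM columns mapped (ref %s)\n",
              nrow(x$rows), nchar(x$rows$seq[1]), nrow(x$column_map), x$ref_id))
  invisible(x)
}

#' Read an aligned family from FASTA
#'
#' @param path Aligned FASTA file (`-` gaps).
#' @param ref_id Reference row id.
#' @param annotation A [reference_annotation()].
#' @return An `aligned_family`.
#' @export
read_alignment <- function(path, ref_id, annotation) {
  aln <- Biostrings::readAAStringSet(path)
  aligned_family(names(aln), unname(as.character(aln)), ref_id, annotation)
}

#' Write an aligned family to FASTA
#' @param f An `aligned_family`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(f, path) {
  aln <- Biostrings::AAStringSet(setNames(f$rows$seq, f$rows$id))
  Biostrings::writeXStringSet(aln, path)
  invisible(path)
}

family_column <- function(f, pos) {
  col <- f$column_map$column[f$column_map$generic == pos]
  if (!length(col)) abort(paste0("generic position ", pos,
                                 " is not mapped to an alignment column"))
  col[1]
}

column_chars <- function(f, col) substr(f$rows$seq, col, col)

#' Conservation of a residue set at a generic position
#'
#' Counts alignment rows carrying one of the queried residues at the
#' column mapped to `pos`.  The primary denominator `N` excludes rows with
#' a gap at that column (conservation among sequences possessing the
#' position); the all-rows percentage is reported alongside so both
#' conventions are visible.
#'
#' @param f An `aligned_family`.
#' @param pos Generic position text, e.g. `"1.50"`.
#' @param residues Character vector of one-letter residue codes (a
#'   residue-class query passes several, e.g. `c("V", "L", "I")`).
#' @return A one-row tibble of class `conservation_result`: `generic`,
#'   `residues`, `n`, `N` (non-gap rows), `percentage` (`100 n / N`),
#'   `n_rows` (all rows) and `percentage_all` (`100 n / n_rows`).
#' @examples
#' ann <- reference_annotation("toy",
#'   data.frame(helix = 1, start = 1, end = 3, anchor = 2))
#' fam <- aligned_family(c("r", "s"), c("ANA", "ANA"), "r", ann)
#' conservation_at(fam, "1.50", "N")
#' @export
conservation_at <- function(f, pos, residues) {
  col <- family_column(f, pos)
  ch <- column_chars(f, col)
  non_gap <- ch != "-"
  n <- sum(ch %in% toupper(residues))
  N <- sum(non_gap)
  out <- tibble(
    generic = pos,
    residues = paste(toupper(residues), collapse = ""),
    n = n, N = N,
    percentage = if (N > 0) 100 * n / N else 0,
    n_rows = length(ch),
    percentage_all = 100 * n / length(ch)
  )
  class(out) <- c("conservation_result", class(out))
  out
}

#' Motif specifications
#'
#' A motif is a set of constraints `(generic position, allowed residues)`;
#' a sequence matches when every constrained position carries one of the
#' allowed residues (a gap always fails).  Alternatives are expressed by
#' multi-residue allowed sets, e.g. `D` or `E` at 3.49.
#'
#' @param name Motif name.
#' @param generic Character vector of generic positions.
#' @param allowed Character vector (same length) of allowed residue sets,
#'   each a string of one-letter codes, e.g. `"DE"`.
#' @param family Optional family tag.
#' @return An object of class `motif_spec`.
#' @examples
#' motif_spec("TM3_DRY", c("3.49", "3.50", "3.51"), c("DE", "R", "Y"))
#' @export
motif_spec <- function(name, generic, allowed, family = NA_character_) {
  if (length(generic) != length(allowed)) {
    abort("generic and allowed must have the same length")
  }
  if (anyDuplicated(generic)) abort("motif positions must be distinct")
  if (any(nchar(allowed) == 0)) abort("allowed residue sets must be non-empty")
  parse_generic(generic)  # validates
  structure(list(name = name,
                 constraints = tibble(generic = generic,
                                      allowed = toupper(allowed)),
                 family = family),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("<motif_spec> %s: %s\n", x$name,
              paste0(x$constraints$allowed, "^", x$constraints$generic, "^",
                     collapse = " ")))
  invisible(x)
}

#' Shared conserved motifs of the three receptor families
#'
#' The positioned residues of the conserved transmembrane motifs shared by
#' class A GPCRs, human bitter taste receptors (hTAS2Rs) and human odorant
#' receptors (hORs): e.g. the TM1 `N1.50 x x I1.53` of hTAS2Rs, the TM3
#' D/E-R-Y of class A, the TM7 `H7.49 S7.50 x I/V7.52 L7.53` of hTAS2Rs.
#'
#' @param family `"class_a"`, `"htas2r"` or `"hor"`.
#' @return A list of [motif_spec()] objects, one per annotated helix.
#' @export
builtin_motifs <- function(family = c("class_a", "htas2r", "hor")) {
  family <- match.arg(family)
  defs <- switch(family,
    class_a = list(
      TM1 = list(c("1.50", "1.53"), c("N", "V")),
      TM2 = list(c("2.46", "2.50"), c("L", "D")),
      TM3 = list(c("3.49", "3.50", "3.51"), c("DE", "R", "Y")),
      TM4 = list("4.50", "W"),
      TM5 = list("5.50", "P"),
      TM6 = list(c("6.44", "6.48", "6.50"), c("F", "W", "P")),
      TM7 = list(c("7.49", "7.50", "7.53"), c("N", "P", "Y"))
    ),
    htas2r = list(
      TM1 = list(c("1.50", "1.53"), c("N", "I")),
      TM2 = list(c("2.46", "2.50"), c("L", "R")),
      TM3 = list(c("3.46", "3.49", "3.50", "3.53"), c("L", "F", "Y", "K")),
      TM5 = list(c("5.39", "5.42", "5.43", "5.50"), c("L", "S", "L", "P")),
      TM6 = list(c("6.44", "6.48"), c("F", "Y")),
      TM7 = list(c("7.49", "7.50", "7.52", "7.53"), c("H", "S", "IV", "L"))
    ),
    hor = list(
      TM1 = list(c("1.49", "1.50", "1.53"), c("G", "N", "I")),
      TM2 = list(c("2.46", "2.47", "2.50"), c("L", "S", "D")),
      TM3 = list(c("3.49", "3.50", "3.51"), c("DE", "R", "Y")),
      TM4 = list("4.50", "W"),
      TM5 = list(c("5.57", "5.58"), c("S", "Y")),
      TM6 = list("6.40", "H"),
      TM7 = list(c("7.49", "7.50", "7.52", "7.53"), c("N", "P", "IL", "Y"))
    )
  )
  purrr::imap(defs, function(def, nm) {
    motif_spec(paste0(family, "_", nm), def[[1]], def[[2]], family = family)
  })
}

#' Read motif specifications from TSV
#'
#' TSV with header `name generic allowed` (one row per constraint, grouped
#' into motifs by `name`).
#'
#' @param path File path.
#' @return A list of `motif_spec` objects.
#' @export
read_motifs <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), generic = readr::col_character(),
    allowed = readr::col_character()
  ))
  lapply(split(df, df$name), function(g) {
    motif_spec(g$name[1], g$generic, g$allowed)
  })
}

#' Scan an aligned family for a motif
#'
#' @param f An `aligned_family`.
#' @param motif A [motif_spec()]; every constrained position must be mapped
#'   to a column.
#' @return A list with `passes` (tibble `id`, `pass`), `fraction` (passing
#'   rows / all rows) and `name`.
#' @export
scan_motif <- function(f, motif) {
  cons <- motif$constraints
  unmapped <- cons$generic[!cons$generic %in% f$column_map$generic]
  if (length(unmapped)) {
    abort(paste0("motif position(s) not mapped to a column: ",
                 paste(unmapped, collapse = ", ")))
  }
  pass <- rep(TRUE, nrow(f$rows))
  for (i in seq_len(nrow(cons))) {
    ch <- column_chars(f, family_column(f, cons$generic[i]))
    allowed <- strsplit(cons$allowed[i], "")[[1]]
    pass <- pass & ch %in% allowed  # gap is never allowed
  }
  list(passes = tibble(id = f$rows$id, pass = pass),
       fraction = mean(pass), name = motif$name)
}

#' Curate a family alignment
#'
#' Discards rows with a large gap fraction over the mapped transmembrane
#' columns, or lacking the required conserved motifs — emulating the
#' removal of unannotated pseudogenes and mispredicted open reading frames
#' from a receptor-family alignment.
#'
#' @param f An `aligned_family`.
#' @param gap_frac_max Maximum tolerated gap fraction over TM columns
#'   (default 0.2).
#' @param required List of [motif_spec()]s a sequence should carry.
#' @param min_motifs Minimum number of required motifs a row must pass
#'   (default: all of them).
#' @return A list with `retained` (ids) and `rejected` (tibble `id`,
#'   `reason`).
#' @export
curate_family <- function(f, gap_frac_max = 0.2, required = list(),
                          min_motifs = length(required)) {
  if (gap_frac_max <= 0 || gap_frac_max > 1) {
    abort("gap_frac_max must be in (0, 1]")
  }
  tm_cols <- f$column_map$column
  gap_frac <- vapply(f$rows$seq, function(s) {
    ch <- strsplit(s, "")[[1]][tm_cols]
    mean(ch == "-")
  }, double(1), USE.NAMES = FALSE)

  n_pass <- rep(0L, nrow(f$rows))
  for (m in required) {
    n_pass <- n_pass + as.integer(scan_motif(f, m)$passes$pass)
  }
  gap_bad <- gap_frac > gap_frac_max
  motif_bad <- n_pass < min_motifs
  reason <- dplyr::case_when(
    gap_bad & motif_bad ~ "gap fraction; missing conserved features",
    gap_bad ~ "gap fraction",
    motif_bad ~ "missing conserved features",
    TRUE ~ NA_character_
  )
  list(
    retained = f$rows$id[!gap_bad & !motif_bad],
    rejected = tibble(id = f$rows$id, reason = reason) |>
      filter(!is.na(.data$reason))
  )
}

#' Keep only some rows of an aligned family
#' @param f An `aligned_family`.
#' @param ids Ids to retain (the reference row is always kept).
#' @return A new `aligned_family`.
#' @export
subset_family <- function(f, ids) {
  keep <- f$rows$id %in% union(ids, f$ref_id)
  aligned_family(f$rows$id[keep], f$rows$seq[keep], f$ref_id, f$annotation)
}
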