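#' Generic residue positions
#'
#' Generic (Ballesteros-Weinstein / GPCRdb-style) positions label
#' transmembrane residues as `helix.offset`, anchored so that the most
#' conserved residue of each helix is `X.50`.  They make residues comparable
#' across receptors and against mutagenesis records.
#'
#' @param helix Integer 1-7.
#' @param offset Integer 1-99 (the anchor residue has offset 50).
#' @return The text form, e.g. `"7.52"`.
#' @examples
#' generic_position(7, 52)
#' parse_generic("7.52")
#' @export
generic_position <- function(helix, offset) {
  helix <- as.integer(helix)
  offset <- as.integer(offset)
  if (any(helix < 1 | helix > 7, na.rm = TRUE)) abort("helix must be in 1..7")
  if (any(offset < 1 | offset > 99, na.rm = TRUE)) abort("offset must be in 1..99")
  sprintf("%d.%d", helix, offset)
}

#' @rdname generic_position
#' @param text Character vector of `"h.oo"` labels.
#' @return For `parse_generic()`, a tibble with columns `generic`, `helix`,
#'   `offset`.
#' @export
parse_generic <- function(text) {
  m <- regmatches(text, regexec("^([1-7])\\.([0-9]{1,2})$", text))
  bad <- lengths(m) != 3
  if (any(bad)) {
    abort(paste0("not a generic position label: ",
                 paste(text[bad], collapse = ", ")))
  }
  helix <- vapply(m, function(x) as.integer(x[2]), integer(1))
  offset <- vapply(m, function(x) as.integer(x[3]), integer(1))
  if (any(offset < 1)) abort("offset must be in 1..99")
  tibble(generic = generic_position(helix, offset), helix = helix,
         offset = offset)
}

#' Reference annotation for generic numbering
#'
#' Describes the template used to project generic numbers: per-helix
#' transmembrane spans and the sequence index of each `X.50` anchor, all in
#' ungapped template-sequence coordinates.
#'
#' @param template_id Template identifier (e.g. a PDB code).
#' @param spans A data frame with columns `helix` (1-7), `start`, `end`,
#'   `anchor` (sequence indices, `start <= anchor <= end`), one row per
#'   helix, spans ordered and non-overlapping.
#' @param sequence Optional template sequence (one-letter, ungapped); when
#'   given, alignments are checked against it.
#' @return An object of class `reference_annotation`.
#' @export
reference_annotation <- function(template_id, spans, sequence = NULL) {
  spans <- as_tibble(spans)[, c("helix", "start", "end", "anchor")]
  spans <- mutate(spans, across(dplyr::everything(), as.integer))
  spans <- arrange(spans, .data$helix)
  if (anyDuplicated(spans$helix)) abort("duplicate helix in spans")
  if (any(spans$start > spans$end)) abort("span start > end")
  if (any(spans$anchor < spans$start | spans$anchor > spans$end)) {
    abort("anchor outside its TM span")
  }
  if (nrow(spans) > 1) {
    if (any(spans$start[-1] <= spans$end[-nrow(spans)])) {
      abort("TM spans overlap or are out of order")
    }
  }
  structure(list(template_id = template_id, spans = spans,
                 sequence = sequence),
            class = "reference_annotation")
}

#' @export
print.reference_annotation <- function(x, ...) {
  cat(sprintf("<reference_annotation> template %s, %d helices\n",
              x$template_id, nrow(x$spans)))
  print(x$spans)
  invisible(x)
}

#' Read a reference annotation from YAML
#'
#' The file holds `template_id`, optional `sequence`, and a `spans` list of
#' maps with keys `helix`, `start`, `end`, `anchor`.
#'
#' @param path Path to the YAML file.
#' @return A `reference_annotation`.
#' @export
read_reference_annotation <- function(path) {
  y <- yaml::read_yaml(path)
  reference_annotation(
    template_id = y$template_id,
    spans = dplyr::bind_rows(lapply(y$spans, as_tibble)),
    sequence = y$sequence
  )
}

new_numbering_map <- function(df, unmapped = NULL) {
  df <- as_tibble(df)
  needed <- c("chain", "seqnum", "res_key", "helix", "offset", "generic")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(paste0("numbering map missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$res_key) || anyDuplicated(df$generic)) {
    abort("numbering map must be one-to-one")
  }
  mono <- df |>
    arrange(.data$helix, .data$seqnum) |>
    group_by(.data$helix) |>
    summarise(ok = all(diff(.data$offset) > 0) || n() == 1, .groups = "drop")
  if (!all(mono$ok)) {
    abort("offsets must strictly increase with sequence number within a helix")
  }
  attr(df, "unmapped") <- unmapped %||%
    tibble(seqnum = integer(), reason = character())
  class(df) <- c("numbering_map", class(df))
  df
}

#' Unmapped residues of a numbering map
#' @param map A `numbering_map`.
#' @return Tibble of `seqnum`, `reason`.
#' @export
unmapped_residues <- function(map) attr(map, "unmapped")

#' Assign generic numbers to a target sequence from a pairwise alignment
#'
#' Projects the template's generic numbering onto a target: a target residue
#' aligned within a helix's transmembrane span receives
#' `offset = 50 + (distance from the X.50 anchor, counted in template
#' positions)`.  Target residues aligned to template gaps (insertions) are
#' unmapped; if the target row has a gap at a helix's anchor column the
#' whole helix is left unmapped for that target; offsets falling outside
#' 1..99 are unmapped rather than clamped.
#'
#' @param target_row,reference_row Aligned sequences (equal length, `-` for
#'   gaps) from the same alignment; the reference row is the template.
#' @param ann A [reference_annotation()] for the template.
#' @param chain Chain id to use in residue keys (default `"A"`).
#' @param seq_start Sequence number of the first target residue (default 1).
#' @return A `numbering_map` tibble (`chain`, `seqnum`, `res_key`, `helix`,
#'   `offset`, `generic`) with unmapped residues in
#'   [unmapped_residues()].
#' @examples
#' ann <- reference_annotation("toy",
#'   data.frame(helix = 1, start = 1, end = 7, anchor = 4))
#' assign_generic_numbers("MNLLIAV", "MNLLIAV", ann)
#' @export
assign_generic_numbers <- function(target_row, reference_row, ann,
                                   chain = "A", seq_start = 1L) {
  tgt <- strsplit(toupper(target_row), "")[[1]]
  ref <- strsplit(toupper(reference_row), "")[[1]]
  if (length(tgt) != length(ref)) {
    abort("target and reference rows must come from the same alignment (equal length)")
  }
  if (!is.null(ann$sequence)) {
    if (paste(ref[ref != "-"], collapse = "") != toupper(ann$sequence)) {
      abort("reference row does not match the annotation's template sequence")
    }
  }
  ref_pos <- ifelse(ref == "-", NA_integer_, cumsum(ref != "-"))
  tgt_pos <- ifelse(tgt == "-", NA_integer_, cumsum(tgt != "-"))

  spans <- ann$spans
  if (any(spans$anchor > max(ref_pos, na.rm = TRUE))) {
    abort("annotation anchor beyond the end of the reference sequence")
  }
  anchor_col <- vapply(spans$anchor, function(p) which(ref_pos == p)[1],
                       integer(1))
  if (any(is.na(anchor_col))) abort("anchor column gapped in reference")

  helix_of <- rep(NA_integer_, length(ref))
  for (h in seq_len(nrow(spans))) {
    helix_of[!is.na(ref_pos) & ref_pos >= spans$start[h] &
               ref_pos <= spans$end[h]] <- spans$helix[h]
  }
  anchor_gapped <- setNames(tgt[anchor_col] == "-", spans$helix)

  mapped <- list()
  unmapped <- list()
  for (i in which(!is.na(tgt_pos))) {
    sn <- seq_start + tgt_pos[i] - 1L
    if (is.na(ref_pos[i]) || is.na(helix_of[i])) next  # insertion or loop
    h <- helix_of[i]
    if (isTRUE(anchor_gapped[[as.character(h)]])) {
      unmapped[[length(unmapped) + 1L]] <-
        tibble(seqnum = sn, reason = "anchor column gapped in target")
      next
    }
    off <- 50L + ref_pos[i] - spans$anchor[spans$helix == h]
    if (off < 1L || off > 99L) {
      unmapped[[length(unmapped) + 1L]] <-
        tibble(seqnum = sn, reason = "offset outside 1..99")
      next
    }
    mapped[[length(mapped) + 1L]] <-
      tibble(chain = chain, seqnum = sn,
             res_key = res_key(chain, sn),
             helix = as.integer(h), offset = off,
             generic = generic_position(h, off))
  }
  empty <- tibble(chain = character(), seqnum = integer(),
                  res_key = character(), helix = integer(),
                  offset = integer(), generic = character())
  new_numbering_map(bind_rows(c(list(empty), mapped)),
                    unmapped = bind_rows(unmapped))
}

#' Residue at a generic position
#'
#' Inverse lookup of a numbering map.
#'
#' @param map A `numbering_map`.
#' @param pos Generic position text (e.g. `"2.50"`).
#' @return The residue key, or `NA_character_` when the position is
#'   unmapped.
#' @export
residue_at <- function(map, pos) {
  hit <- map$res_key[map$generic == pos]
  if (length(hit)) hit[1] else NA_character_
}

#' Generic position of a residue
#'
#' @param map A `numbering_map`.
#' @param key Residue key(s).
#' @return Generic position text, `NA` where unmapped.
#' @export
generic_of <- function(map, key) {
  map$generic[match(key, map$res_key)]
}
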