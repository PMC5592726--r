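#' Active/inactive structure pairs
#'
#' A `state_pair` couples two structures of the same receptor solved in
#' different activation states with their numbering maps, so side-chain
#' contact maps can be compared in generic-position space across receptors.
#' State labels are always taken from the inputs (the manifest or the
#' constructor arguments), never inferred from structure identifiers.
#'
#' @param receptor Receptor identifier.
#' @param active,inactive `structure_model`s of the two states.
#' @param map_active,map_inactive `numbering_map`s for the two structures.
#' @param provenance Optional character vector (e.g. PDB codes).
#' @return An object of class `state_pair`.
#' @export
state_pair <- function(receptor, active, inactive, map_active, map_inactive,
                       provenance = NULL) {
  stopifnot(inherits(active, "structure_model"),
            inherits(inactive, "structure_model"))
  if (!inherits(map_active, "numbering_map") ||
      !inherits(map_inactive, "numbering_map")) {
    abort("both structures must carry a numbering map")
  }
  structure(list(receptor = receptor, active = active, inactive = inactive,
                 map_active = map_active, map_inactive = map_inactive,
                 provenance = provenance),
            class = "state_pair")
}

#' @export
print.state_pair <- function(x, ...) {
  cat(sprintf("<state_pair> %s: active %s / inactive %s\n", x$receptor,
              x$active$id, x$inactive$id))
  invisible(x)
}

#' Aggregate contact rewiring across activation-state pairs
#'
#' For every receptor pair, builds the side-chain contact maps of the
#' active and inactive structures, takes their difference in
#' generic-position space, and tallies how many receptors gain or lose each
#' generic contact pair upon activation.  A pair enters the report when it
#' changes (in either direction) in at least `min_support` receptors.
#'
#' @param pairs List of [state_pair()] objects.
#' @param vdw A [vdw_table()].
#' @param thresholds A [contact_thresholds()].
#' @param min_support Minimum number of receptor pairs in which a generic
#'   contact pair must change (default 3, a majority of a five-receptor
#'   panel).
#' @return An object of class `rewiring_report`: list with `pairs` (tibble
#'   `pos_a`, `pos_b`, `support`, `n_gained`, `n_lost`), `involvement`
#'   (tibble `generic`, `count` over reported pairs), `n_state_pairs`, and
#'   `dropped` (contacts lost to unmapped residues, per receptor).
#' @export
aggregate_rewiring <- function(pairs, vdw = vdw_table(),
                               thresholds = contact_thresholds(),
                               min_support = 3L) {
  if (!length(pairs)) abort("need at least one state pair")
  if (min_support < 1) abort("min_support must be >= 1")
  per_receptor <- purrr::imap(pairs, function(p, idx) {
    cm_a <- build_contact_map(p$active, vdw, thresholds)
    cm_i <- build_contact_map(p$inactive, vdw, thresholds)
    d <- diff_contact_maps(cm_a, cm_i, p$map_active, p$map_inactive)
    list(
      changes = bind_rows(
        mutate(d$gained, direction = "gained"),
        mutate(d$lost, direction = "lost")
      ) |>
        mutate(receptor = p$receptor, pair_id = idx),
      dropped = tibble(receptor = p$receptor, dropped = sum(d$dropped))
    )
  })
  changes <- bind_rows(purrr::map(per_receptor, "changes"))
  dropped <- bind_rows(purrr::map(per_receptor, "dropped"))

  if (nrow(changes)) {
    tallied <- changes |>
      group_by(.data$pos_a, .data$pos_b) |>
      summarise(
        support = dplyr::n_distinct(.data$pair_id),
        n_gained = sum(.data$direction == "gained"),
        n_lost = sum(.data$direction == "lost"),
        .groups = "drop"
      ) |>
      filter(.data$support >= min_support) |>
      arrange(desc(.data$support), .data$pos_a, .data$pos_b)
  } else {
    tallied <- tibble(pos_a = character(), pos_b = character(),
                      support = integer(), n_gained = integer(),
                      n_lost = integer())
  }
  involvement <- tibble(generic = c(tallied$pos_a, tallied$pos_b)) |>
    dplyr::count(.data$generic, name = "count") |>
    arrange(desc(.data$count), .data$generic)

  structure(list(pairs = tallied, involvement = involvement,
                 n_state_pairs = length(pairs),
                 min_support = as.integer(min_support),
                 dropped = dropped),
            class = "rewiring_report")
}

#' @export
print.rewiring_report <- function(x, ...) {
  cat(sprintf("<rewiring_report> %d generic pair(s) changing in >= %d of %d receptor pairs\n",
              nrow(x$pairs), x$min_support, x$n_state_pairs))
  if (nrow(x$pairs)) print(x$pairs)
  invisible(x)
}

#' @export
tidy.rewiring_report <- function(x, ...) x$pairs

#' @export
glance.rewiring_report <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs),
         n_positions = nrow(x$involvement),
         n_state_pairs = x$n_state_pairs,
         min_support = x$min_support)
}

#' Rank conserved positions by involvement in activation rewiring
#'
#' Keeps the generic positions of a rewiring report whose conservation
#' meets a threshold, ordered by how many reported rewired pairs involve
#' them (ties broken by helix then offset).  Positions below the threshold
#' are listed separately rather than silently dropped.
#'
#' @param report A `rewiring_report`.
#' @param conservation A tibble binding rows of [conservation_at()] results
#'   (or any tibble with `generic` and `percentage`), covering every
#'   reported position.
#' @param min_conservation Conservation percentage required (default 70).
#' @return A list with `ranked` and `below_threshold` tibbles (`generic`,
#'   `count`, `percentage`).
#' @export
rank_activation_positions <- function(report, conservation,
                                      min_conservation = 70) {
  inv <- report$involvement
  missing <- setdiff(inv$generic, conservation$generic)
  if (length(missing)) {
    abort(paste0("no conservation entry for position(s): ",
                 paste(missing, collapse = ", ")))
  }
  joined <- inv |>
    left_join(select(as_tibble(conservation), "generic", "percentage"),
              by = "generic") |>
    bind_cols(parse_generic(inv$generic)[c("helix", "offset")]) |>
    arrange(desc(.data$count), .data$helix, .data$offset) |>
    select("generic", "count", "percentage")
  list(
    ranked = filter(joined, .data$percentage >= min_conservation),
    below_threshold = filter(joined, .data$percentage < min_conservation)
  )
}

#' Read a state-pair manifest
#'
#' TSV with header `receptor active_pdb inactive_pdb numbering_ref`: paths
#' to the two structure files and to a YAML reference annotation used to
#' number both (via an identity alignment of each structure's sequence is
#' not assumed — the manifest's annotation applies to structures whose
#' sequence numbering matches the template's).
#'
#' @param path Manifest TSV path.
#' @return A tibble with one row per receptor pair.
#' @export
read_state_manifest <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    receptor = readr::col_character(),
    active_pdb = readr::col_character(),
    inactive_pdb = readr::col_character(),
    numbering_ref = readr::col_character()
  ))
}

#' Write a rewiring report (TSV + JSON)
#' @param report A `rewiring_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_rewiring <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(report$pairs, tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      pairs = report$pairs, involvement = report$involvement,
      n_state_pairs = report$n_state_pairs, min_support = report$min_support
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(tsv_path, json_path))
}
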