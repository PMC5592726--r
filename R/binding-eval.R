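#' Mutagenesis records
#'
#' Site-directed mutagenesis results used as the experimental reference:
#' each record says whether mutating one residue shifted the agonist's
#' half-maximal effective concentration (EC50).  A residue is classed
#' `affects_response` when any of its mutations shifts EC50 at least
#' `fold_threshold`-fold (or abolishes the response, `ec50_fold = Inf`),
#' `no_effect` when an explicit no-shift measurement exists.
#'
#' @param receptor Receptor identifier.
#' @param seqnum Residue sequence number.
#' @param generic Generic position label or `NA`.
#' @param mutation Mutation string, e.g. `"N24A"`.
#' @param effect `"affects_response"` or `"no_effect"`; may be `NA` when
#'   `ec50_fold` is supplied, in which case it is derived.
#' @param ec50_fold Positive fold-change of EC50 upon mutation (`Inf` for an
#'   abolished response), or `NA`.
#' @param source Free-text provenance.
#' @param fold_threshold Fold-change at or above which a mutation counts as
#'   affecting the response (default 2).
#' @param chain Chain id used to form residue keys (default `"A"`).
#' @return A tibble of class `mutagenesis_records`.
#' @export
mutagenesis_records <- function(receptor, seqnum, mutation,
                                effect = NA_character_,
                                generic = NA_character_,
                                ec50_fold = NA_real_,
                                source = NA_character_,
                                fold_threshold = 2, chain = "A") {
  df <- tibble(
    receptor = as.character(receptor), seqnum = as.integer(seqnum),
    generic = as.character(generic), mutation = as.character(mutation),
    effect = as.character(effect), ec50_fold = as.double(ec50_fold),
    source = as.character(source)
  )
  if (any(!is.na(df$ec50_fold) & df$ec50_fold <= 0)) {
    abort("ec50_fold must be positive")
  }
  derived <- as.character(ifelse(is.na(df$ec50_fold), NA_character_,
                                 ifelse(df$ec50_fold >= fold_threshold,
                                        "affects_response", "no_effect")))
  df$effect <- dplyr::coalesce(df$effect, derived)
  if (any(is.na(df$effect))) {
    abort("each record needs an effect class or an ec50_fold value")
  }
  bad <- !is.na(derived) & df$effect != derived
  if (any(bad)) {
    abort(paste0("effect class inconsistent with ec50_fold at threshold ",
                 fold_threshold, " for mutation(s): ",
                 paste(df$mutation[bad], collapse = ", ")))
  }
  if (!all(df$effect %in% c("affects_response", "no_effect"))) {
    abort("effect must be 'affects_response' or 'no_effect'")
  }
  if (anyDuplicated(df[c("seqnum", "mutation")])) {
    abort("one record per (residue, mutation) allowed")
  }
  df$res_key <- res_key(chain, df$seqnum)
  class(df) <- c("mutagenesis_records", class(df))
  df
}

#' Read / write mutagenesis tables
#'
#' TSV with header
#' `receptor residue_seqnum generic_position mutation effect ec50_fold source`.
#'
#' @param path File path.
#' @param fold_threshold,chain Passed to [mutagenesis_records()].
#' @return A `mutagenesis_records` tibble (read) or `path` (write).
#' @export
read_mutagenesis <- function(path, fold_threshold = 2, chain = "A") {
  df <- readr::read_tsv(path, col_types = readr::cols(
    receptor = readr::col_character(),
    residue_seqnum = readr::col_integer(),
    generic_position = readr::col_character(),
    mutation = readr::col_character(),
    effect = readr::col_character(),
    ec50_fold = readr::col_double(),
    source = readr::col_character()
  ))
  mutagenesis_records(
    receptor = df$receptor, seqnum = df$residue_seqnum,
    generic = df$generic_position, mutation = df$mutation,
    effect = df$effect, ec50_fold = df$ec50_fold, source = df$source,
    fold_threshold = fold_threshold, chain = chain
  )
}

#' @rdname read_mutagenesis
#' @param records A `mutagenesis_records` tibble.
#' @export
write_mutagenesis <- function(records, path) {
  out <- tibble(
    receptor = records$receptor, residue_seqnum = records$seqnum,
    generic_position = records$generic, mutation = records$mutation,
    effect = records$effect, ec50_fold = records$ec50_fold,
    source = records$source
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Residues in the extracellular (top) half of the bundle
#'
#' Projects each polymer residue's C-alpha onto the bundle axis and keeps
#' residues at or above the centroid projection — the side holding the
#' canonical orthosteric binding site given the axis orientation from
#' [bundle_axis()].  Residues at exactly the midpoint are included; a
#' residue without a C-alpha is excluded with a warning.
#'
#' @param s A `structure_model`.
#' @param axis_info A list with `axis` and `centroid`, from
#'   [bundle_axis()]; computed from `s` when omitted.
#' @return Character vector of residue keys.
#' @export
top_half_residues <- function(s, axis_info = NULL) {
  axis_info <- axis_info %||% bundle_axis(s)
  rs <- filter(residues(s), .data$record_class == "polymer")
  ca <- filter(s$atoms, .data$record_class == "polymer", .data$name == "CA")
  no_ca <- setdiff(rs$res_key, ca$res_key)
  if (length(no_ca)) {
    warn(paste0("residue(s) without C-alpha excluded from top-half test: ",
                paste(no_ca, collapse = ", ")))
  }
  proj <- as.vector(coords_matrix(ca) %*% axis_info$axis)
  c0 <- sum(axis_info$centroid * axis_info$axis)
  ca$res_key[proj >= c0]
}

#' Evaluate predicted ligand contacts against mutagenesis data
#'
#' Experimentally tested residues in the top half of the receptor are
#' classified by agreement between the structural prediction (residue in
#' contact with the ligand, optionally required to pass the chemical
#' filter) and the measured EC50 effect:
#' TP = affects response and predicted; FN = affects response, not
#' predicted; FP = no effect but predicted; TN = no effect, not predicted.
#' A residue with both affecting and non-affecting mutations counts as
#' `affects_response`.  Predicted contacts at residues never tested
#' experimentally are reported separately and never enter the counts.
#'
#' @param contacts A `ligand_contacts` tibble from
#'   [detect_ligand_contacts()].
#' @param records A `mutagenesis_records` tibble.
#' @param top_half Character vector of residue keys (from
#'   [top_half_residues()]).
#' @param require_chemical Only contacts passing the chemical filter count
#'   as predictions (default `TRUE`).
#' @param known_residues Optional character vector of all residue keys in
#'   the structure; when given, records referencing unknown residues raise
#'   an error listing them.
#' @return An object of class `binding_eval`: a list with `counts`
#'   (TP/FP/TN/FN), `precision`, `recall`, `predictive_power`, `ledger`
#'   (per-residue outcome tibble) and `untested_contacts`.
#' @export
evaluate_complex <- function(contacts, records, top_half,
                             require_chemical = TRUE,
                             known_residues = NULL) {
  if (!is.null(known_residues)) {
    missing <- setdiff(unique(records$res_key), known_residues)
    if (length(missing)) {
      abort(paste0("mutagenesis record(s) reference residues absent from ",
                   "the structure: ", paste(missing, collapse = ", ")))
    }
  }
  predicted <- contacts$res_key[
    if (require_chemical) contacts$passes_chemical_filter else TRUE]

  tested <- records |>
    as_tibble() |>
    group_by(.data$res_key) |>
    summarise(
      seqnum = .data$seqnum[1],
      generic = .data$generic[!is.na(.data$generic)][1] %||% NA_character_,
      effect = if (any(.data$effect == "affects_response"))
        "affects_response" else "no_effect",
      n_mutations = n(), .groups = "drop"
    ) |>
    filter(.data$res_key %in% top_half) |>
    mutate(
      predicted = .data$res_key %in% predicted,
      outcome = dplyr::case_when(
        .data$effect == "affects_response" & .data$predicted ~ "TP",
        .data$effect == "affects_response" & !.data$predicted ~ "FN",
        .data$effect == "no_effect" & .data$predicted ~ "FP",
        TRUE ~ "TN"
      )
    ) |>
    arrange(.data$seqnum)

  counts <- c(TP = sum(tested$outcome == "TP"),
              FP = sum(tested$outcome == "FP"),
              TN = sum(tested$outcome == "TN"),
              FN = sum(tested$outcome == "FN"))
  res <- list(
    counts = counts,
    precision = precision(counts),
    recall = recall(counts),
    predictive_power = if (sum(counts) > 0) predictive_power(counts) else NA_real_,
    ledger = tested,
    untested_contacts = setdiff(predicted, tested$res_key)
  )
  class(res) <- "binding_eval"
  res
}

check_counts <- function(c) {
  c <- unlist(c)
  needed <- c("TP", "FP", "TN", "FN")
  if (!all(needed %in% names(c))) {
    abort("counts need named entries TP, FP, TN, FN")
  }
  c <- c[needed]
  if (any(c < 0) || any(c != round(c))) abort("counts must be non-negative integers")
  c
}

#' Precision, recall and predictive power from confusion counts
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`, both defined
#' as 0 when their denominator is 0.  `predictive_power` is the percentage
#' of experimentally tested residues whose prediction agrees with
#' experiment, `(TP + TN) * 100 / (TP + FP + TN + FN)`; it errors when no
#' residue was tested.
#'
#' @param counts Named vector or list with `TP`, `FP`, `TN`, `FN`.
#' @return A single number (fraction for precision/recall, percentage for
#'   predictive power).
#' @examples
#' precision(c(TP = 3, FP = 1, TN = 2, FN = 0))  # 0.75
#' recall(c(TP = 2, FP = 0, TN = 3, FN = 1))     # 0.667
#' @export
precision <- function(counts) {
  c <- check_counts(counts)
  if (c[["TP"]] + c[["FP"]] == 0) 0 else c[["TP"]] / (c[["TP"]] + c[["FP"]])
}

#' @rdname precision
#' @export
recall <- function(counts) {
  c <- check_counts(counts)
  if (c[["TP"]] + c[["FN"]] == 0) 0 else c[["TP"]] / (c[["TP"]] + c[["FN"]])
}

#' @rdname precision
#' @export
predictive_power <- function(counts) {
  c <- check_counts(counts)
  total <- sum(c)
  if (total == 0) abort("no experimentally tested residues: predictive power undefined")
  (c[["TP"]] + c[["TN"]]) * 100 / total
}

#' Round half away from zero (report display convention)
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2, the convention used when
#'   comparing metrics against published tables).
#' @return Rounded values.
#' @export
round_metric <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' @export
print.binding_eval <- function(x, ...) {
  cat("<binding_eval>\n  counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  cat(sprintf("  precision %.2f  recall %.2f  predictive power %.1f%%\n",
              round_metric(x$precision), round_metric(x$recall),
              if (is.na(x$predictive_power)) NA else x$predictive_power))
  if (length(x$untested_contacts)) {
    cat("  untested predicted contacts:",
        paste(x$untested_contacts, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.binding_eval <- function(x, ...) x$ledger

#' @export
glance.binding_eval <- function(x, ...) {
  tibble(
    TP = x$counts[["TP"]], FP = x$counts[["FP"]],
    TN = x$counts[["TN"]], FN = x$counts[["FN"]],
    precision = x$precision, recall = x$recall,
    predictive_power = x$predictive_power,
    n_tested = nrow(x$ledger),
    n_untested_contacts = length(x$untested_contacts)
  )
}

#' Write an evaluation report
#'
#' Writes the per-residue ledger as TSV and the summary (counts and
#' metrics) as JSON.
#'
#' @param eval A `binding_eval`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_evaluation <- function(eval, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(eval$ledger, tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      counts = as.list(eval$counts),
      precision = eval$precision, recall = eval$recall,
      predictive_power = eval$predictive_power,
      untested_contacts = eval$untested_contacts
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(tsv_path, json_path))
}
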