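#' Run configuration
#'
#' A validated configuration shared by all pipeline stages.  Every
#' threshold lives here; stages read no hidden constants.  Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param x A named list (e.g. from [yaml::read_yaml()]) or a YAML file
#'   path.
#' @return An object of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(paste0("config file not found: ", x),
                               class = "gpcr_missing_input")
    x <- yaml::read_yaml(x)
  }
  known <- c("thresholds", "seed", "paths", "effect_fold_threshold",
             "min_support", "min_conservation", "gap_frac_max", "min_motifs",
             "simulate", "require_chemical", "his_protonated")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "gpcr_config_error")
  }
  cfg <- list(
    thresholds = as_contact_thresholds(x$thresholds),
    seed = as.integer(x$seed %||% 1L),
    paths = x$paths %||% list(),
    effect_fold_threshold = x$effect_fold_threshold %||% 2,
    min_support = as.integer(x$min_support %||% 3L),
    min_conservation = x$min_conservation %||% 70,
    gap_frac_max = x$gap_frac_max %||% 0.2,
    min_motifs = x$min_motifs,
    simulate = x$simulate %||% list(),
    require_chemical = isTRUE(x$require_chemical %||% TRUE),
    his_protonated = isTRUE(x$his_protonated)
  )
  structure(cfg, class = "run_config")
}

config_path <- function(cfg, name, required = TRUE) {
  p <- cfg$paths[[name]]
  if (is.null(p)) {
    if (required) abort(paste0("config paths.", name, " is required"),
                        class = "gpcr_config_error")
    return(NULL)
  }
  if (required && !file.exists(p)) {
    abort(paste0("input not found: ", p), class = "gpcr_missing_input")
  }
  p
}

# atomic write: render to a sibling temp file, then rename into place
write_atomic <- function(write_fn, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  write_fn(tmp)
  file.rename(tmp, path)
  path
}

#' Run one pipeline stage
#'
#' Orchestrates the package's functions as named stages with file inputs
#' and outputs, writing every artifact atomically plus a JSON run manifest
#' (config hash, seed, package version) sufficient to reproduce the run.
#' Outputs are a pure function of config + seed, so reruns are
#' byte-identical.
#'
#' Stages: `simulate` (generate a complex, descriptor, mutagenesis table
#' and truth under `paths$out_dir`), `contacts` (detect ligand contacts),
#' `evaluate` (score contacts against mutagenesis data), `numbering`
#' (generic numbers for an aligned target), `conserve` (conservation at
#' positions), `curate` (family curation), `rewire` (state-pair rewiring
#' aggregation), `report` (bundle evaluation summaries).
#'
#' @param stage Stage name.
#' @param config A [run_config()], a named list, or a YAML path.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$paths$out_dir` or `"."`.
#' @return Invisibly, a named character vector of artifact paths.
#' @export
run_stage <- function(stage = c("simulate", "contacts", "evaluate",
                                "numbering", "conserve", "curate",
                                "rewire", "report"),
                      config = run_config(), out_dir = NULL) {
  stage <- match.arg(stage)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- out_dir %||% cfg$paths$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(out_dir, name)

  artifacts <- switch(stage,
    simulate = stage_simulate(cfg, out),
    contacts = stage_contacts(cfg, out),
    evaluate = stage_evaluate(cfg, out),
    numbering = stage_numbering(cfg, out),
    conserve = stage_conserve(cfg, out),
    curate = stage_curate(cfg, out),
    rewire = stage_rewire(cfg, out),
    report = stage_report(cfg, out)
  )
  manifest <- out(paste0(stage, "_manifest.json"))
  # the hash covers the run's parameters and input identities, not where
  # the files happen to live, so reruns are byte-identical across dirs
  hashed <- unclass(cfg)
  hashed$paths$out_dir <- NULL
  hashed$paths <- lapply(hashed$paths, function(p)
    if (is.character(p)) basename(p) else p)
  write_atomic(function(tmp) {
    jsonlite::write_json(list(
      stage = stage,
      seed = cfg$seed,
      config_hash = rlang::hash(hashed),
      package_version = as.character(utils::packageVersion("gpcrcontacts")),
      artifacts = basename(unname(artifacts))
    ), tmp, auto_unbox = TRUE, pretty = TRUE)
  }, manifest)
  invisible(c(artifacts, manifest = manifest))
}

stage_simulate <- function(cfg, out) {
  sim <- cfg$simulate
  n_contacts <- unlist(sim$n_contacts %||%
                         list(hbond = 1, salt_bridge = 1,
                              aromatic_stacking = 1, hydrophobic = 1))
  cx <- gen_bundle_complex(cfg$seed, n_contacts = n_contacts,
                           n_decoys = sim$n_decoys %||% 5,
                           thresholds = cfg$thresholds)
  intended <- unlist(sim$intended %||% list(TP = 2, FP = 1, TN = 2, FN = 1))
  mt <- gen_mutagenesis_table(cx$truth, intended, cfg$seed)
  c(
    pdb = write_atomic(function(p) writeLines(cx$pdb, p), out("complex.pdb")),
    descriptor = write_atomic(function(p) write_ligand_descriptor(cx$descriptor, p),
                              out("ligand_descriptor.tsv")),
    mutagenesis = write_atomic(function(p) write_mutagenesis(mt$records, p),
                               out("mutagenesis.tsv")),
    truth = write_atomic(function(p) readr::write_tsv(cx$truth, p),
                         out("truth.tsv"))
  )
}

stage_contacts <- function(cfg, out) {
  s <- read_structure(config_path(cfg, "pdb"))
  d <- read_ligand_descriptor(config_path(cfg, "descriptor"))
  contacts <- detect_ligand_contacts(s, descriptor = d,
                                     thresholds = cfg$thresholds,
                                     his_protonated = cfg$his_protonated)
  c(contacts = write_atomic(function(p) write_contacts(contacts, p),
                            out("contacts.tsv")))
}

stage_evaluate <- function(cfg, out) {
  s <- read_structure(config_path(cfg, "pdb"))
  contacts <- readr::read_tsv(config_path(cfg, "contacts"),
                              col_types = readr::cols())
  records <- read_mutagenesis(config_path(cfg, "mutagenesis"),
                              fold_threshold = cfg$effect_fold_threshold)
  if (!nrow(records)) {
    abort("mutagenesis table is empty: nothing to evaluate",
          class = "gpcr_config_error")
  }
  ev <- evaluate_complex(contacts, records, top_half_residues(s),
                         require_chemical = cfg$require_chemical,
                         known_residues = residues(s)$res_key)
  ledger <- out("evaluation_ledger.tsv")
  json <- out("evaluation.json")
  write_atomic(function(p) readr::write_tsv(ev$ledger, p), ledger)
  write_atomic(function(p) write_evaluation(ev, json_path = p), json)
  c(ledger = ledger, json = json)
}

stage_numbering <- function(cfg, out) {
  ann <- read_reference_annotation(config_path(cfg, "annotation"))
  aln <- Biostrings::readAAStringSet(config_path(cfg, "alignment"))
  if (length(aln) < 2) abort("alignment needs a reference and a target row",
                             class = "gpcr_config_error")
  map <- assign_generic_numbers(as.character(aln[[2]]),
                                as.character(aln[[1]]), ann)
  c(numbering = write_atomic(function(p) readr::write_tsv(as_tibble(map), p),
                             out("numbering.tsv")))
}

stage_conserve <- function(cfg, out) {
  ann <- read_reference_annotation(config_path(cfg, "annotation"))
  fam <- read_alignment(config_path(cfg, "alignment"),
                        ref_id = cfg$paths$ref_id %||% NULL, annotation = ann)
  queries <- readr::read_tsv(config_path(cfg, "positions"),
                             col_types = readr::cols(
                               generic = readr::col_character(),
                               residues = readr::col_character()
                             ))
  res <- purrr::map2(queries$generic, queries$residues, function(g, r) {
    conservation_at(fam, g, strsplit(r, "")[[1]])
  }) |> bind_rows()
  c(conservation = write_atomic(function(p) readr::write_tsv(res, p),
                                out("conservation.tsv")))
}

stage_curate <- function(cfg, out) {
  ann <- read_reference_annotation(config_path(cfg, "annotation"))
  fam <- read_alignment(config_path(cfg, "alignment"),
                        ref_id = cfg$paths$ref_id %||% NULL, annotation = ann)
  motifs_path <- config_path(cfg, "motifs", required = FALSE)
  required <- if (is.null(motifs_path)) anchor_motifs(ann) else
    read_motifs(motifs_path)
  cur <- curate_family(fam, gap_frac_max = cfg$gap_frac_max,
                       required = required,
                       min_motifs = cfg$min_motifs %||% length(required))
  c(
    retained = write_atomic(function(p)
      readr::write_tsv(tibble(id = cur$retained), p), out("retained.tsv")),
    rejected = write_atomic(function(p) readr::write_tsv(cur$rejected, p),
                            out("rejected.tsv"))
  )
}

stage_rewire <- function(cfg, out) {
  manifest <- read_state_manifest(config_path(cfg, "manifest"))
  pairs <- purrr::pmap(manifest, function(receptor, active_pdb, inactive_pdb,
                                          numbering_ref) {
    ann <- read_reference_annotation(numbering_ref)
    map <- assign_generic_numbers(ann$sequence, ann$sequence, ann)
    state_pair(receptor,
               active = read_structure(active_pdb, state_label = "active"),
               inactive = read_structure(inactive_pdb, state_label = "inactive"),
               map_active = map, map_inactive = map,
               provenance = c(active_pdb, inactive_pdb))
  })
  rep <- aggregate_rewiring(pairs, thresholds = cfg$thresholds,
                            min_support = cfg$min_support)
  tsv <- out("rewiring.tsv")
  json <- out("rewiring.json")
  write_atomic(function(p) write_rewiring(rep, tsv_path = p), tsv)
  write_atomic(function(p) write_rewiring(rep, json_path = p), json)
  c(tsv = tsv, json = json)
}

stage_report <- function(cfg, out) {
  ev <- jsonlite::read_json(config_path(cfg, "evaluation"))
  counts <- unlist(ev$counts)
  summary <- tibble(
    TP = counts[["TP"]], FP = counts[["FP"]],
    TN = counts[["TN"]], FN = counts[["FN"]],
    precision = round_metric(ev$precision),
    recall = round_metric(ev$recall),
    predictive_power = ev$predictive_power
  )
  c(report = write_atomic(function(p) readr::write_tsv(summary, p),
                          out("report.tsv")))
}
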