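#' Synthetic seven-helix bundles with planted ground truth
#'
#' Seeded generators produce every input the pipeline consumes — PDB
#' structures, ligand descriptors, mutagenesis tables, family alignments,
#' activation-state pairs — with known, planted truth, so every stage can be
#' tested end-to-end without external data.  Helices are idealized (C-alpha
#' rise 1.5 Angstrom per residue, 100 degree turn, helix radius 2.3,
#' bundle radius 12); side chains are 1-6 pseudo-atoms with correct element
#' types so the distance and chemistry rules engage exactly.  Realism is not
#' the goal; rule engagement with verified margins is.
#'
#' @name synthetic_data
#' @keywords internal
NULL

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

BUNDLE <- list(
  n_helix = 7L, n_per_helix = 25L, rise = 1.5, turn_deg = 100,
  helix_radius = 2.3, bundle_radius = 12, cb_len = 1.0,
  anchor_index = 13L
)

#' Reference annotation of the synthetic seven-helix template
#'
#' Seven contiguous 25-residue transmembrane spans with the `X.50` anchor at
#' the 13th residue of each helix; the template sequence is the synthetic
#' consensus carrying bitter-taste-receptor-flavoured conserved motifs
#' (N1.50, R2.50, F3.49-Y3.50, S5.42, F6.44-Y6.48, H7.49-S7.50-I7.52-L7.53).
#'
#' @return A [reference_annotation()].
#' @export
default_reference <- function() {
  n <- BUNDLE$n_per_helix
  spans <- tibble(
    helix = 1:7,
    start = (0:6) * n + 1L,
    end = (1:7) * n,
    anchor = (0:6) * n + BUNDLE$anchor_index
  )
  reference_annotation("SYNTH7TM", spans, sequence = synth_consensus())
}

#' Consensus sequence of the synthetic template
#' @return A 175-character one-letter sequence.
#' @export
synth_consensus <- function() {
  n <- BUNDLE$n_per_helix
  seq <- rep("L", 7L * n)
  at <- function(h, off) (h - 1L) * n + BUNDLE$anchor_index + (off - 50L)
  seq[at(1, 50)] <- "N"; seq[at(1, 53)] <- "I"
  seq[at(2, 46)] <- "L"; seq[at(2, 50)] <- "R"
  seq[at(3, 46)] <- "L"; seq[at(3, 49)] <- "F"; seq[at(3, 50)] <- "Y"
  seq[at(3, 53)] <- "K"
  seq[at(4, 50)] <- "W"
  seq[at(5, 39)] <- "L"; seq[at(5, 42)] <- "S"; seq[at(5, 43)] <- "L"
  seq[at(5, 50)] <- "P"
  seq[at(6, 44)] <- "F"; seq[at(6, 48)] <- "Y"; seq[at(6, 50)] <- "A"
  seq[at(7, 49)] <- "H"; seq[at(7, 50)] <- "S"; seq[at(7, 52)] <- "I"
  seq[at(7, 53)] <- "L"
  paste(seq, collapse = "")
}

#' Generic numbering map of the synthetic bundle
#'
#' Self-alignment of the synthetic template against its own annotation;
#' residue `seqnum` runs 1..175 on chain A.
#'
#' @param annotation A [reference_annotation()]; defaults to
#'   [default_reference()].
#' @return A `numbering_map`.
#' @export
synthetic_numbering_map <- function(annotation = default_reference()) {
  cons <- annotation$sequence
  assign_generic_numbers(cons, cons, annotation)
}

# C-alpha position of residue i (1..25) of helix h (1..7); odd helices run
# extracellular (top, +z) to intracellular, even helices the reverse
helix_ca <- function(h, i) {
  p <- BUNDLE
  theta <- 2 * pi * (h - 1) / p$n_helix
  centre <- p$bundle_radius * c(cos(theta), sin(theta))
  z_half <- (p$n_per_helix - 1) * p$rise / 2
  z <- if (h %% 2 == 1) z_half - (i - 1) * p$rise else -z_half + (i - 1) * p$rise
  phi <- (i - 1) * p$turn_deg * pi / 180 + theta
  c(centre + p$helix_radius * c(cos(phi), sin(phi)), z)
}

default_cb <- function(ca) {
  inward <- -c(ca[1], ca[2], 0)
  inward <- inward / sqrt(sum(inward^2))
  ca + BUNDLE$cb_len * inward
}

unitv <- function(v) v / sqrt(sum(v^2))
orth_basis <- function(u) {
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- unitv(pracma_cross(u, a))
  w <- unitv(pracma_cross(u, v))
  list(v = v, w = w)
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# base bundle atom rows (backbone + default CB), resnames from the consensus
base_bundle_atoms <- function() {
  cons <- strsplit(synth_consensus(), "")[[1]]
  n <- 7L * BUNDLE$n_per_helix
  sn <- seq_len(n)
  h <- (sn - 1L) %/% BUNDLE$n_per_helix + 1L
  i <- (sn - 1L) %% BUNDLE$n_per_helix + 1L
  ca <- t(mapply(helix_ca, h, i))
  res3 <- unname(AA1_TO_3[cons])
  block <- function(name, element, offset) {
    tibble(name = name, element = element,
           x = ca[, 1] + offset[1], y = ca[, 2] + offset[2],
           z = ca[, 3] + offset[3],
           chain = "A", seqnum = sn, resname = res3,
           record_class = "polymer")
  }
  inward <- -ca[, 1:2] / sqrt(rowSums(ca[, 1:2]^2))
  cb <- tibble(name = "CB", element = "C",
               x = ca[, 1] + BUNDLE$cb_len * inward[, 1],
               y = ca[, 2] + BUNDLE$cb_len * inward[, 2],
               z = ca[, 3],
               chain = "A", seqnum = sn, resname = res3,
               record_class = "polymer") |>
    filter(.data$resname != "GLY")
  bind_rows(
    block("N", "N", c(0, 0, 0.9)),
    block("CA", "C", c(0, 0, 0)),
    block("C", "C", c(0.7, 0.7, -0.7)),
    block("O", "O", c(1.0, 1.0, -1.4)),
    cb
  ) |>
    arrange(.data$seqnum, match(.data$name, c("N", "CA", "C", "O", "CB")))
}

finish_structure <- function(atom_rows, id, state_label = "unspecified") {
  atom_rows |>
    mutate(
      serial = row_number(),
      occupancy = 1, altloc = "", icode = "",
      x = round(.data$x, 3), y = round(.data$y, 3), z = round(.data$z, 3)
    ) |>
    new_structure_model(id = id, state_label = state_label)
}

# ligand: compact agonist-like hetero group near the top of the bundle.
# Atom roles are declared in the descriptor: N1 (+1, donor), O1 (acceptor),
# C7 (apolar), C1..C6 (aromatic ring).
synthetic_ligand <- function(z0 = 9, rot = 0) {
  R <- function(v) {  # rotate xy by `rot`
    c(cos(rot) * v[1] - sin(rot) * v[2],
      sin(rot) * v[1] + cos(rot) * v[2], v[3])
  }
  pos <- list(
    N1 = c(1.5, 0, z0 + 0.8),
    O1 = c(-1.5, 0, z0 + 0.8),
    C7 = c(0, 1.5, z0 - 0.8)
  )
  ring_centre <- c(0, -1.2, z0 - 0.4)
  for (k in 1:6) {
    ang <- (k - 1) * pi / 3
    pos[[paste0("C", k)]] <- ring_centre + 1.2 * c(cos(ang), sin(ang), 0)
  }
  pos <- lapply(pos, R)
  elements <- c(N1 = "N", O1 = "O", C7 = "C",
                setNames(rep("C", 6), paste0("C", 1:6)))
  atoms <- purrr::imap(pos, function(p, nm) {
    tibble(name = nm, element = elements[[nm]], x = p[1], y = p[2], z = p[3],
           chain = "L", seqnum = 1L, resname = "LIG",
           record_class = "hetero")
  }) |> bind_rows()
  desc <- ligand_descriptor(
    atom_name = c("N1", "O1", "C7", paste0("C", 1:6)),
    charge = c(1L, 0L, 0L, rep(0L, 6)),
    ring_id = c(NA, NA, NA, rep(1L, 6)),
    donor = c(TRUE, rep(FALSE, 8)),
    acceptor = c(FALSE, TRUE, rep(FALSE, 7)),
    apolar = c(FALSE, FALSE, TRUE, rep(FALSE, 6))
  )
  list(atoms = atoms, descriptor = desc,
       targets = list(
         hbond = pos$O1, salt_bridge = pos$N1, hydrophobic = pos$C7,
         aromatic_stacking = R(ring_centre)
       ))
}

# residue types and interaction atoms planted for each label
plant_sidechain <- function(label, ca, target, thresholds) {
  t <- thresholds
  u <- unitv(ca - target)
  switch(label,
    hbond = {
      og <- target + (t$hbond_max - 0.3) * u
      list(resname = "SER",
           atoms = list(CB = list((ca + og) / 2, "C"), OG = list(og, "O")))
    },
    salt_bridge = {
      od1 <- target + (t$salt_bridge_max - 0.3) * u
      list(resname = "ASP",
           atoms = list(CB = list((ca + od1) / 2, "C"),
                        OD1 = list(od1, "O"),
                        OD2 = list(od1 + 1.0 * u, "O")))
    },
    hydrophobic = {
      cd1 <- target + (t$hydrophobic_max - 0.3) * u
      list(resname = "LEU",
           atoms = list(CB = list(default_cb(ca), "C"),
                        CG = list((ca + cd1) / 2, "C"),
                        CD1 = list(cd1, "C")))
    },
    aromatic_stacking = {
      centre <- target + (t$ring_centroid_max - 0.3) * u
      b <- orth_basis(u)
      ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      atoms <- list(CB = list((ca + centre) / 2, "C"))
      for (k in 1:6) {
        ang <- (k - 1) * pi / 3
        atoms[[ring_names[k]]] <-
          list(centre + 1.39 * (cos(ang) * b$v + sin(ang) * b$w), "C")
      }
      list(resname = "PHE", atoms = atoms)
    },
    abort(paste0("unknown interaction label: ", label))
  )
}

# available planting slots: residues whose C-alpha sits in the upper
# binding-site band of each helix
contact_slots <- function() {
  z_half <- (BUNDLE$n_per_helix - 1) * BUNDLE$rise / 2
  slots <- list()
  for (h in 1:7) {
    for (i in seq_len(BUNDLE$n_per_helix)) {
      ca <- helix_ca(h, i)
      if (ca[3] >= 6 && ca[3] <= 12) {
        slots[[length(slots) + 1L]] <- tibble(
          helix = h, i = i,
          seqnum = (h - 1L) * BUNDLE$n_per_helix + i,
          azimuth = atan2(sin(2 * pi * (h - 1) / 7), cos(2 * pi * (h - 1) / 7)),
          z = ca[3]
        )
      }
    }
  }
  bind_rows(slots)
}

decoy_candidates <- function() {
  out <- list()
  for (h in 1:7) {
    for (i in seq_len(BUNDLE$n_per_helix)) {
      ca <- helix_ca(h, i)
      if (ca[3] >= 1.5 && ca[3] <= 4.5) {
        out[[length(out) + 1L]] <- (h - 1L) * BUNDLE$n_per_helix + i
      }
    }
  }
  unlist(out)
}

#' Generate a synthetic receptor-ligand complex with planted contacts
#'
#' Builds an idealized seven-helix bundle with a compact agonist-like
#' ligand in the canonical extracellular binding site.  The requested
#' number of contact residues per interaction label are planted with their
#' decisive atom 0.3 Angstrom inside the label's cutoff; decoy residues are
#' guaranteed at least 0.5 Angstrom outside the 5.5 Angstrom contact rule.
#' All margins are re-verified by brute force on the emitted (rounded)
#' coordinates; violations raise an error rather than producing a bad
#' fixture.
#'
#' @param seed Integer seed; the generator is a pure function of
#'   `(seed, parameters)`.
#' @param n_contacts Named integer vector: how many residues to plant per
#'   label among `hbond`, `salt_bridge`, `aromatic_stacking`,
#'   `hydrophobic`.
#' @param n_decoys Number of decoy (guaranteed non-contact, top-half)
#'   residues to record.
#' @param thresholds A [contact_thresholds()].
#' @return A list: `structure` (a `structure_model`), `pdb` (PDB text
#'   lines), `descriptor` (a [ligand_descriptor()]), `ligand_key`, `truth`
#'   (tibble `res_key`, `seqnum`, `resname`, `role`, `label`), `map` (the
#'   bundle's `numbering_map`) and `annotation`.
#' @examples
#' cx <- gen_bundle_complex(1, n_contacts = c(hbond = 1), n_decoys = 2)
#' cx$truth
#' @export
gen_bundle_complex <- function(seed,
                               n_contacts = c(hbond = 1, salt_bridge = 1,
                                              aromatic_stacking = 1,
                                              hydrophobic = 1),
                               n_decoys = 5,
                               thresholds = contact_thresholds()) {
  t <- as_contact_thresholds(thresholds)
  labels <- c("hbond", "salt_bridge", "aromatic_stacking", "hydrophobic")
  n_contacts <- n_contacts[intersect(names(n_contacts), labels)]
  if (any(n_contacts < 0)) abort("label counts must be >= 0")
  n_contacts <- n_contacts[n_contacts > 0]

  with_seed(seed, {
    rot <- runif(1, 0, 2 * pi)
    z0 <- runif(1, 8.5, 9.5)
    lig <- synthetic_ligand(z0 = z0, rot = rot)

    slots <- contact_slots()
    if (sum(n_contacts) > nrow(slots)) {
      abort("infeasible packing: more planted contacts than available slots")
    }
    # assign each planted contact to the free slot whose helix azimuth best
    # faces its ligand target atom, preferring C-alpha heights near the
    # target
    assignments <- list()
    free <- rep(TRUE, nrow(slots))
    for (lab in names(n_contacts)) {
      target <- lig$targets[[lab]]
      taz <- atan2(target[2], target[1])
      for (k in seq_len(n_contacts[[lab]])) {
        dang <- abs(((slots$azimuth - taz + pi) %% (2 * pi)) - pi)
        score <- dang + 0.05 * abs(slots$z - target[3]) + runif(nrow(slots), 0, 1e-3)
        score[!free] <- Inf
        pick <- which.min(score)
        free[pick] <- FALSE
        assignments[[length(assignments) + 1L]] <-
          mutate(slots[pick, ], label = lab)
      }
    }
    assignments <- bind_rows(assignments)

    atoms <- base_bundle_atoms()
    if (nrow(assignments)) {
      for (r in seq_len(nrow(assignments))) {
        sn <- assignments$seqnum[r]
        lab <- assignments$label[r]
        ca <- helix_ca(assignments$helix[r], assignments$i[r])
        sc <- plant_sidechain(lab, ca, lig$targets[[lab]], t)
        atoms <- filter(atoms, !(.data$seqnum == sn & !.data$name %in% BACKBONE_ATOMS))
        atoms$resname[atoms$seqnum == sn] <- sc$resname
        extra <- purrr::imap(sc$atoms, function(a, nm) {
          tibble(name = nm, element = a[[2]], x = a[[1]][1], y = a[[1]][2],
                 z = a[[1]][3], chain = "A", seqnum = sn,
                 resname = sc$resname, record_class = "polymer")
        }) |> bind_rows()
        atoms <- bind_rows(atoms, extra)
      }
    }
    atoms <- arrange(atoms, .data$seqnum,
                     match(.data$name, c(BACKBONE_ATOMS,
                                         sort(unique(atoms$name)))))

    planted_sn <- if (nrow(assignments)) assignments$seqnum else integer()
    pool <- setdiff(decoy_candidates(), planted_sn)
    if (n_decoys > length(pool)) {
      abort("infeasible packing: not enough decoy candidates")
    }
    decoys <- sort(sample(pool, n_decoys))

    s <- finish_structure(bind_rows(atoms, lig$atoms),
                          id = sprintf("synth_complex_seed%d", seed))
    truth <- bind_rows(
      if (nrow(assignments)) tibble(
        seqnum = assignments$seqnum,
        role = "contact", label = assignments$label
      ),
      if (length(decoys)) tibble(seqnum = decoys, role = "decoy",
                                 label = NA_character_)
    )
    if (nrow(truth)) {
      truth <- truth |>
        mutate(res_key = res_key("A", .data$seqnum)) |>
        left_join(select(residues(s), "res_key", "resname"), by = "res_key") |>
        select("res_key", "seqnum", "resname", "role", "label") |>
        arrange(.data$seqnum)
    } else {
      truth <- tibble(res_key = character(), seqnum = integer(),
                      resname = character(), role = character(),
                      label = character())
    }
    verify_complex_truth(s, lig$descriptor, truth, t)
    list(structure = s, pdb = structure_to_pdb(s),
         descriptor = lig$descriptor, ligand_key = "L:1", truth = truth,
         map = synthetic_numbering_map(), annotation = default_reference())
  })
}

# brute-force margin verification on emitted coordinates; independent
# double loops over atoms, no reuse of the detection code path
verify_complex_truth <- function(s, descriptor, truth, t, margin = 0.25) {
  lat <- filter(s$atoms, .data$res_key == "L:1", .data$element != "H")
  L <- coords_matrix(lat)
  d <- descriptor
  heavy <- filter(s$atoms, .data$element != "H")
  blocks <- split(seq_len(nrow(heavy)), heavy$res_key)
  min_to_ligand <- function(key) {
    at <- heavy[blocks[[key]], ]
    best <- Inf
    for (i in seq_len(nrow(at))) {
      for (j in seq_len(nrow(L))) {
        dd <- sqrt(sum((c(at$x[i], at$y[i], at$z[i]) - L[j, ])^2))
        if (dd < best) best <- dd
      }
    }
    best
  }
  rule_distances <- function(key) {
    at <- filter(s$atoms, .data$res_key == key, .data$element != "H")
    rn <- at$resname[1]
    pdist <- function(an, ln) {
      a <- filter(at, .data$name %in% an)
      l <- lat[lat$name %in% ln, ]
      if (!nrow(a) || !nrow(l)) return(Inf)
      best <- Inf
      for (i in seq_len(nrow(a))) for (j in seq_len(nrow(l))) {
        dd <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                          c(l$x[j], l$y[j], l$z[j]))^2))
        best <- min(best, dd)
      }
      best
    }
    hb <- min(pdist(sidechain_donors[[rn]], d$atom_name[d$acceptor]),
              pdist(sidechain_acceptors[[rn]], d$atom_name[d$donor]))
    chg <- sidechain_charges[[rn]]
    sb <- if (is.null(chg) || rn == "HIS") Inf else
      pdist(chg$atoms, d$atom_name[!is.na(d$charge) & d$charge * chg$charge < 0])
    ring <- sidechain_rings[[rn]]
    ar <- Inf
    ra <- filter(at, .data$name %in% ring)
    if (nrow(ra) >= 3) {
      rc <- colMeans(coords_matrix(ra))
      for (rid in unique(d$ring_id[!is.na(d$ring_id)])) {
        lr <- lat[lat$name %in% d$atom_name[!is.na(d$ring_id) & d$ring_id == rid], ]
        lc <- colMeans(coords_matrix(lr))
        ar <- min(ar, sqrt(sum((rc - lc)^2)))
      }
    }
    hp <- pdist(sidechain_apolar_carbons[[rn]], d$atom_name[d$apolar])
    c(hbond = hb, salt_bridge = sb, aromatic_stacking = ar, hydrophobic = hp)
  }
  cutoffs <- c(hbond = t$hbond_max, salt_bridge = t$salt_bridge_max,
               aromatic_stacking = t$ring_centroid_max,
               hydrophobic = t$hydrophobic_max)
  planted <- filter(truth, .data$role == "contact")
  for (r in seq_len(nrow(planted))) {
    key <- planted$res_key[r]; lab <- planted$label[r]
    if (min_to_ligand(key) >= t$ligand_contact_cutoff - margin) {
      abort(paste0("planted contact ", key, " misses the distance rule"))
    }
    rd <- rule_distances(key)
    if (rd[[lab]] > cutoffs[[lab]] - margin) {
      abort(paste0("planted ", lab, " at ", key, " misses its margin"))
    }
    others <- setdiff(names(cutoffs), lab)
    if (any(rd[others] <= cutoffs[others])) {
      abort(paste0("planted ", lab, " at ", key,
                   " satisfies an unintended interaction rule"))
    }
  }
  polymer <- filter(residues(s), .data$record_class == "polymer")
  non_planted <- setdiff(polymer$res_key, planted$res_key)
  for (key in non_planted) {
    if (min_to_ligand(key) < t$ligand_contact_cutoff + 0.4) {
      abort(paste0("non-planted residue ", key,
                   " intrudes into the contact shell"))
    }
  }
  outside <- setdiff(truth$res_key, top_half_residues(s))
  if (length(outside)) {
    abort(paste0("planted residue(s) not in the top half: ",
                 paste(outside, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Generate a mutagenesis table realizing a planted confusion matrix
#'
#' Assigns `affects_response` to `TP` planted-contact residues and `FN`
#' decoys, `no_effect` to `FP` planted-contact residues and `TN` decoys
#' (all in the top half by construction), so that evaluating the complex
#' recovers exactly the intended counts.
#'
#' @param truth The `truth` tibble from [gen_bundle_complex()].
#' @param intended Named vector `c(TP=, FP=, TN=, FN=)`.
#' @param seed Integer seed (residue sampling and EC50 fold-changes).
#' @param receptor Receptor id written into the records.
#' @return A list: `records` (a [mutagenesis_records()] tibble) and
#'   `scenario` (the intended counts plus chosen residues).
#' @export
gen_mutagenesis_table <- function(truth, intended, seed,
                                  receptor = "synthetic") {
  intended <- check_counts(intended)
  contacts <- filter(truth, .data$role == "contact")
  decoys <- filter(truth, .data$role == "decoy")
  if (intended[["TP"]] + intended[["FP"]] > nrow(contacts)) {
    abort("unrealizable: TP + FP exceeds the number of planted contacts")
  }
  if (intended[["FN"]] + intended[["TN"]] > nrow(decoys)) {
    abort("unrealizable: FN + TN exceeds the number of decoys")
  }
  with_seed(seed + 1L, {
    ci <- sample(nrow(contacts))
    di <- sample(nrow(decoys))
    pick <- bind_rows(
      if (intended[["TP"]]) mutate(contacts[ci[seq_len(intended[["TP"]])], ],
                                   effect = "affects_response"),
      if (intended[["FP"]]) mutate(contacts[ci[intended[["TP"]] + seq_len(intended[["FP"]])], ],
                                   effect = "no_effect"),
      if (intended[["FN"]]) mutate(decoys[di[seq_len(intended[["FN"]])], ],
                                   effect = "affects_response"),
      if (intended[["TN"]]) mutate(decoys[di[intended[["FN"]] + seq_len(intended[["TN"]])], ],
                                   effect = "no_effect")
    )
    if (is.null(pick) || !nrow(pick)) {
      records <- mutagenesis_records(character(), integer(), character())
      return(list(records = records,
                  scenario = list(intended = intended, residues = pick)))
    }
    fold <- ifelse(pick$effect == "affects_response",
                   round(runif(nrow(pick), 3, 40), 1),
                   round(runif(nrow(pick), 1, 1.6), 2))
    records <- mutagenesis_records(
      receptor = receptor,
      seqnum = pick$seqnum,
      mutation = paste0(AA3_TO_1[pick$resname], pick$seqnum, "A"),
      effect = pick$effect,
      ec50_fold = fold,
      source = "synthetic"
    )
    list(records = records,
         scenario = list(intended = intended, residues = pick))
  })
}

#' Generate a synthetic family alignment with planted column frequencies
#'
#' Rows are copies of the synthetic consensus; at each profiled generic
#' position, exactly `round(frequency * n_rows)` rows (chosen by seeded
#' shuffle) carry the profiled residue and the remaining rows carry a
#' different one, so conservation values are known by construction.
#' Gap-defective rows replace a leading fraction of TM columns with gaps;
#' motif-defective rows lose every `X.50` anchor residue.  The first row is
#' never made defective and serves as the alignment's reference.
#'
#' @param seed Integer seed.
#' @param n_rows Number of sequences.
#' @param profiles A data frame (or tibble) with columns `generic`,
#'   `residue`, `frequency`.
#' @param n_gap_defective Rows to corrupt with gaps.
#' @param gap_frac Gap fraction planted in defective rows (default 0.4).
#' @param n_motif_defective Rows to corrupt at all anchor columns.
#' @param annotation A [reference_annotation()].
#' @return An `aligned_family`; attribute `"truth"` records defective row
#'   ids and realized counts.
#' @export
gen_family_msa <- function(seed, n_rows, profiles = NULL,
                           n_gap_defective = 0, gap_frac = 0.4,
                           n_motif_defective = 0,
                           annotation = default_reference()) {
  if (n_gap_defective + n_motif_defective > n_rows - 1) {
    abort("too many defective rows requested (the reference row must stay clean)")
  }
  cons <- strsplit(annotation$sequence, "")[[1]]
  L <- length(cons)
  with_seed(seed + 2L, {
    m <- matrix(rep(cons, each = n_rows), nrow = n_rows)
    realized <- list()
    if (!is.null(profiles) && nrow(as_tibble(profiles))) {
      profiles <- as_tibble(profiles)
      if (any(profiles$frequency < 0 | profiles$frequency > 1)) {
        abort("profile frequencies must be in [0, 1]")
      }
      for (r in seq_len(nrow(profiles))) {
        g <- parse_generic(profiles$generic[r])
        sp <- annotation$spans[annotation$spans$helix == g$helix, ]
        if (!nrow(sp)) abort(paste0("no span for helix ", g$helix))
        col <- sp$anchor + (g$offset - 50L)
        if (col < sp$start || col > sp$end) {
          abort(paste0("position ", profiles$generic[r], " outside its TM span"))
        }
        res <- toupper(profiles$residue[r])
        count <- floor(profiles$frequency[r] * n_rows + 0.5)
        alt <- if (cons[col] != res) cons[col] else setdiff(c("A", "G"), res)[1]
        rows_with <- sample(n_rows, count)
        m[, col] <- alt
        m[rows_with, col] <- res
        realized[[length(realized) + 1L]] <- tibble(
          generic = profiles$generic[r], residue = res, count = count
        )
      }
    }
    defective_pool <- sample(2:n_rows)
    gap_rows <- head(defective_pool, n_gap_defective)
    motif_rows <- head(setdiff(defective_pool, gap_rows), n_motif_defective)
    if (length(gap_rows)) {
      k <- ceiling(gap_frac * L)
      m[gap_rows, seq_len(k)] <- "-"
    }
    if (length(motif_rows)) {
      anchors <- annotation$spans$anchor
      for (col in anchors) {
        bad <- if (cons[col] != "G") "G" else "A"
        m[motif_rows, col] <- bad
      }
    }
    ids <- sprintf("seq%03d", seq_len(n_rows))
    fam <- aligned_family(ids, apply(m, 1, paste, collapse = ""),
                          ref_id = ids[1], annotation = annotation)
    attr(fam, "truth") <- list(
      gap_defective = ids[gap_rows],
      motif_defective = ids[motif_rows],
      realized = bind_rows(realized)
    )
    fam
  })
}

#' Anchor-presence motifs of an annotated template
#'
#' One single-position motif per helix requiring the template's own residue
#' at the `X.50` anchor — the minimal "highly conserved features" filter
#' used when curating a synthetic family.
#'
#' @param annotation A [reference_annotation()] carrying a sequence.
#' @return A list of [motif_spec()]s.
#' @export
anchor_motifs <- function(annotation = default_reference()) {
  cons <- strsplit(annotation$sequence, "")[[1]]
  purrr::map(seq_len(nrow(annotation$spans)), function(h) {
    sp <- annotation$spans[h, ]
    motif_spec(sprintf("anchor_%d.50", sp$helix),
               generic_position(sp$helix, 50),
               cons[sp$anchor])
  })
}

#' Flip the contact status of generic-position pairs
#'
#' For each listed pair, moves the two residues' C-beta pseudo-atoms: pairs
#' currently out of side-chain contact are brought together (3.0 Angstrom
#' apart at the midpoint between their C-alphas, at least 0.5 Angstrom
#' inside the van der Waals sum rule); pairs in contact are restored to the
#' default inward-pointing C-beta.  Applying the operation twice restores
#' the original contact pattern.
#'
#' @param s A synthetic `structure_model` (bundle geometry).
#' @param map Its `numbering_map`.
#' @param pairs List of 2-vectors of generic position labels.
#' @param vdw A [vdw_table()].
#' @param thresholds A [contact_thresholds()].
#' @return The modified `structure_model`.
#' @export
rewire_contacts <- function(s, map, pairs, vdw = vdw_table(),
                            thresholds = contact_thresholds()) {
  t <- as_contact_thresholds(thresholds)
  seen <- character()
  atoms <- s$atoms
  for (p in pairs) {
    k1 <- residue_at(map, p[1]); k2 <- residue_at(map, p[2])
    if (is.na(k1) || is.na(k2)) {
      abort(paste0("rewired pair (", p[1], ", ", p[2],
                   ") is not placeable: unmapped position"))
    }
    if (any(c(k1, k2) %in% seen)) {
      abort("geometric conflict: a residue appears in two rewired pairs")
    }
    seen <- c(seen, k1, k2)
    a1 <- filter(atoms, .data$res_key == k1)
    a2 <- filter(atoms, .data$res_key == k2)
    sep <- abs(a1$seqnum[1] - a2$seqnum[1])
    if (a1$chain[1] == a2$chain[1] && sep < t$min_seq_separation) {
      abort("geometric conflict: rewired pair below the sequence-separation floor")
    }
    d <- min_residue_distance(a1, a2, atom_filter = "sidechain_only")
    ca1 <- unlist(filter(a1, .data$name == "CA")[1, c("x", "y", "z")])
    ca2 <- unlist(filter(a2, .data$name == "CA")[1, c("x", "y", "z")])
    in_contact <- d < vdw_radius(vdw, "C") * 2 + t$vdw_tolerance
    if (!in_contact) {
      # meet near the pore axis at the pair's mean height: the bundle
      # interior is empty there, so no third residue can be perturbed
      mid_xy <- (ca1[1:2] + ca2[1:2]) / 2
      if (sqrt(sum(mid_xy^2)) < 1e-6) mid_xy <- c(1, 0)
      meet <- c(2.0 * mid_xy / sqrt(sum(mid_xy^2)), (ca1[3] + ca2[3]) / 2)
      u <- unitv(ca2 - ca1)
      cb1 <- round(meet - 1.5 * u, 3)
      cb2 <- round(meet + 1.5 * u, 3)
    } else {
      cb1 <- round(default_cb(ca1), 3)
      cb2 <- round(default_cb(ca2), 3)
    }
    atoms[atoms$res_key == k1 & atoms$name == "CB", c("x", "y", "z")] <-
      as.list(cb1)
    atoms[atoms$res_key == k2 & atoms$name == "CB", c("x", "y", "z")] <-
      as.list(cb2)
  }
  new_structure_model(atoms, id = s$id, state_label = s$state_label)
}

#' Sample geometrically placeable rewired pairs
#'
#' Proposes generic-position pairs that [gen_state_pair()] can realize
#' without side effects on other contacts: the two residues of a pair sit
#' at the same helix height, and each pair gets its own height band (6
#' Angstrom apart), so planted side chains, which meet near the pore axis
#' at the pair's height, never interfere with one another.
#'
#' @param seed Integer seed.
#' @param n Number of pairs (1-5).
#' @return A list of 2-vectors of generic position labels.
#' @export
rewirable_pairs <- function(seed, n) {
  if (n < 1 || n > 5) abort("n must be between 1 and 5")
  offset_at_z <- function(h, z) {
    for (i in seq_len(BUNDLE$n_per_helix)) {
      if (abs(helix_ca(h, i)[3] - z) < 1e-6) {
        return(50L + i - BUNDLE$anchor_index)
      }
    }
    abort("no residue at the requested helix height")
  }
  with_seed(seed + 3L, {
    z_bands <- sample(c(12, 6, 0, -6, -12), n)
    purrr::map(seq_len(n), function(p) {
      hs <- sample(7, 2)
      c(generic_position(hs[1], offset_at_z(hs[1], z_bands[p])),
        generic_position(hs[2], offset_at_z(hs[2], z_bands[p])))
    })
  })
}

#' Generate an active/inactive state pair with planted contact rewiring
#'
#' The inactive structure is the base bundle (empty side-chain contact
#' map); the active structure additionally forms exactly the listed
#' generic-position contacts, so the contact-map difference is the planted
#' set.  The whole diff is re-verified by brute force before returning.
#'
#' @param seed Integer seed (currently fixes provenance ids; the base
#'   geometry is deterministic).
#' @param rewired List of 2-vectors of generic position labels, e.g.
#'   `list(c("7.52", "1.53"))`.
#' @param receptor Receptor id.
#' @param vdw A [vdw_table()].
#' @param thresholds A [contact_thresholds()].
#' @return A [state_pair()]; attribute `"truth"` holds the canonical
#'   planted pair tibble.
#' @export
gen_state_pair <- function(seed, rewired = list(), receptor = "synthetic",
                           vdw = vdw_table(),
                           thresholds = contact_thresholds()) {
  t <- as_contact_thresholds(thresholds)
  map <- synthetic_numbering_map()
  base <- finish_structure(base_bundle_atoms(),
                           id = sprintf("%s_inactive_seed%d", receptor, seed),
                           state_label = "inactive")
  active <- rewire_contacts(base, map, rewired, vdw, t)
  active$id <- sprintf("%s_active_seed%d", receptor, seed)
  active$state_label <- "active"

  planted <- if (length(rewired)) {
    canonical_generic_pairs(vapply(rewired, `[`, character(1), 1),
                            vapply(rewired, `[`, character(1), 2))
  } else tibble(pos_a = character(), pos_b = character())
  verify_state_pair(active, base, map, planted, vdw, t)

  sp <- state_pair(receptor, active = active, inactive = base,
                   map_active = map, map_inactive = map,
                   provenance = c(active$id, base$id))
  attr(sp, "truth") <- planted
  sp
}

# brute-force all-pairs contact map: explicit residue double loop over
# pre-split side-chain coordinate/radius blocks (generation-time checks and
# test oracles share this path; the production build_contact_map uses a
# single global distance matrix instead)
brute_contact_pairs <- function(s, vdw, t) {
  rs <- filter(residues(s), .data$record_class == "polymer")
  sc <- filter(s$atoms, .data$record_class == "polymer", !.data$is_backbone,
               .data$element != "H")
  blocks <- split(seq_len(nrow(sc)), sc$res_key)
  X <- coords_matrix(sc)
  r <- vdw_radius(vdw, sc$element, sc$name)
  out <- list()
  for (i in seq_len(nrow(rs) - 1)) {
    bi <- blocks[[rs$res_key[i]]]
    if (is.null(bi)) next
    for (j in seq(i + 1, nrow(rs))) {
      if (rs$chain[i] == rs$chain[j] &&
          abs(rs$seqnum[i] - rs$seqnum[j]) < t$min_seq_separation) next
      bj <- blocks[[rs$res_key[j]]]
      if (is.null(bj)) next
      hit <- FALSE
      for (u in bi) {
        dd <- sqrt((X[bj, 1] - X[u, 1])^2 + (X[bj, 2] - X[u, 2])^2 +
                     (X[bj, 3] - X[u, 3])^2)
        if (any(dd < r[u] + r[bj] + t$vdw_tolerance)) {
          hit <- TRUE
          break
        }
      }
      if (hit) {
        out[[length(out) + 1L]] <- tibble(key_i = rs$res_key[i],
                                          key_j = rs$res_key[j])
      }
    }
  }
  bind_rows(out)
}

verify_state_pair <- function(active, inactive, map, planted, vdw, t) {
  pa <- brute_contact_pairs(active, vdw, t)
  pi_ <- brute_contact_pairs(inactive, vdw, t)
  to_generic <- function(df) {
    if (!nrow(df)) return(character())
    g <- canonical_generic_pairs(generic_of(map, df$key_i),
                                 generic_of(map, df$key_j))
    paste(g$pos_a, g$pos_b, sep = "|")
  }
  gained <- setdiff(to_generic(pa), to_generic(pi_))
  lost <- setdiff(to_generic(pi_), to_generic(pa))
  want <- if (nrow(planted)) paste(planted$pos_a, planted$pos_b, sep = "|") else character()
  if (length(lost) || !setequal(gained, want)) {
    abort("state-pair generation failed its brute-force rewiring check")
  }
  invisible(TRUE)
}
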