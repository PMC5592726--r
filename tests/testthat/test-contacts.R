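# a hand-built two-residue + ligand complex used by the rule tests:
# residue geometry is chosen per test around a one-atom "ligand"
mini_complex <- function(res_atoms, resname, lig_atoms, descriptor) {
  lines <- character()
  serial <- 0
  add <- function(record, name, rn, chain, seqnum, xyz, element) {
    serial <<- serial + 1
    lines <<- c(lines, pdb_line(record, serial, name, rn, chain, seqnum,
                                xyz[1], xyz[2], xyz[3], element = element))
  }
  add("ATOM", "CA", resname, "A", 1, c(-8, 0, 0), "C")
  for (nm in names(res_atoms)) {
    el <- if (grepl("^O", nm)) "O" else if (grepl("^N", nm)) "N" else "C"
    add("ATOM", nm, resname, "A", 1, res_atoms[[nm]], el)
  }
  for (nm in names(lig_atoms)) {
    el <- if (grepl("^O", nm)) "O" else if (grepl("^N", nm)) "N" else "C"
    add("HETATM", nm, "LIG", "L", 1, lig_atoms[[nm]], el)
  }
  list(s = parse_structure(c(lines, "END")), descriptor = descriptor)
}

test_that("the 5.5 A contact rule is strict", {
  d <- ligand_descriptor("C1", apolar = TRUE)
  far <- mini_complex(list(CB = c(5.6, 0, 0)), "ALA",
                      list(C1 = c(0, 0, 0)), d)
  near <- mini_complex(list(CB = c(5.4, 0, 0)), "ALA",
                       list(C1 = c(0, 0, 0)), d)
  expect_equal(nrow(detect_ligand_contacts(far$s, descriptor = d)), 0)
  ct <- detect_ligand_contacts(near$s, descriptor = d)
  expect_equal(ct$res_key, "A:1")
  expect_equal(ct$min_dist, 5.4, tolerance = 1e-3)
})

test_that("a serine hydroxyl near a ligand acceptor scores a hydrogen bond", {
  d <- ligand_descriptor("O1", acceptor = TRUE)
  cx <- mini_complex(list(OG = c(3.2, 0, 0)), "SER",
                     list(O1 = c(0, 0, 0)), d)
  ct <- detect_ligand_contacts(cx$s, descriptor = d)
  expect_equal(ct$labels, "hbond")
  expect_true(ct$passes_chemical_filter)
})

test_that("opposite charges within 4 A score a salt bridge", {
  d <- ligand_descriptor("N1", charge = 1L, donor = TRUE)
  cx <- mini_complex(list(OD1 = c(3.7, 0, 0), OD2 = c(4.7, 0, 0)), "ASP",
                     list(N1 = c(0, 0, 0)), d)
  labels <- classify_interaction(residue_atoms(cx$s, "A:1"),
                                 residue_atoms(cx$s, "L:1"), d)
  expect_equal(labels, "salt_bridge")
  # same geometry with a neutral ligand atom: no label at all
  d0 <- ligand_descriptor("N1", charge = 0L)
  expect_equal(classify_interaction(residue_atoms(cx$s, "A:1"),
                                    residue_atoms(cx$s, "L:1"), d0),
               character())
})

test_that("ring centroids within 5 A score aromatic stacking", {
  ring_names <- paste0("C", 1:6)
  lig_ring <- setNames(lapply(1:6, function(k) {
    1.2 * c(cos(k * pi / 3), sin(k * pi / 3), 0)
  }), ring_names)
  d <- ligand_descriptor(ring_names, ring_id = 1L)
  phe_ring <- setNames(lapply(1:6, function(k) {
    c(4, 0, 0) + 1.39 * c(0, cos(k * pi / 3), sin(k * pi / 3))
  }), c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))
  cx <- mini_complex(phe_ring, "PHE", lig_ring, d)
  labels <- classify_interaction(residue_atoms(cx$s, "A:1"),
                                 residue_atoms(cx$s, "L:1"), d)
  expect_true("aromatic_stacking" %in% labels)
})

test_that("backbone polar proximity yields no label; apolar carbons do", {
  # Leu CD1 4.2 A from an apolar ligand carbon, while the backbone O sits
  # 3 A from a ligand donor: only the hydrophobic rule may fire
  d <- ligand_descriptor(c("C1", "N1"), charge = c(0L, 0L),
                         donor = c(FALSE, TRUE), apolar = c(TRUE, FALSE))
  lines <- c(
    pdb_line("ATOM", 1, "CA", "LEU", "A", 1, -8, 0, 0, element = "C"),
    pdb_line("ATOM", 2, "O", "LEU", "A", 1, 0, 3, 0, element = "O"),
    pdb_line("ATOM", 3, "CD1", "LEU", "A", 1, 4.2, 0, 0, element = "C"),
    pdb_line("HETATM", 4, "C1", "LIG", "L", 1, 0, 0, 0, element = "C"),
    pdb_line("HETATM", 5, "N1", "LIG", "L", 1, 0, 0.5, 0, element = "N"),
    "END"
  )
  s <- parse_structure(lines)
  labels <- classify_interaction(residue_atoms(s, "A:1"),
                                 residue_atoms(s, "L:1"), d)
  expect_equal(labels, "hydrophobic")
})

test_that("planted complexes give exactly the planted contacts and labels", {
  for (seed in c(31, 32)) {
    cx <- gen_bundle_complex(seed, n_contacts = c(hbond = 2, salt_bridge = 1,
                                                  aromatic_stacking = 1,
                                                  hydrophobic = 2),
                             n_decoys = 4)
    ct <- detect_ligand_contacts(cx$structure, descriptor = cx$descriptor)
    planted <- cx$truth[cx$truth$role == "contact", ]
    expect_setequal(ct$res_key, planted$res_key)
    expect_equal(ct$labels[match(planted$res_key, ct$res_key)],
                 planted$label)
    expect_true(all(ct$passes_chemical_filter))
    # the pure distance rule agrees with the brute-force oracle
    expect_setequal(ct$res_key,
                    oracle_contact_residues(cx$structure, cx$ligand_key))
  }
})

test_that("ligand contacts are invariant under rigid-body motion", {
  cx <- gen_bundle_complex(33, n_decoys = 3)
  ct1 <- detect_ligand_contacts(cx$structure, descriptor = cx$descriptor)
  ct2 <- detect_ligand_contacts(rigid_transform(cx$structure),
                                descriptor = cx$descriptor)
  expect_equal(ct1$res_key, ct2$res_key)
  expect_equal(ct1$labels, ct2$labels)
  expect_equal(ct1$min_dist, ct2$min_dist, tolerance = 1e-6)
})

test_that("raising cutoffs never removes contacts", {
  cx <- gen_bundle_complex(34, n_decoys = 3)
  t1 <- contact_thresholds()
  t2 <- contact_thresholds(ligand_contact_cutoff = 7, hbond_max = 4.5,
                           salt_bridge_max = 5, ring_centroid_max = 6,
                           hydrophobic_max = 5.5)
  c1 <- detect_ligand_contacts(cx$structure, descriptor = cx$descriptor,
                               thresholds = t1)
  c2 <- detect_ligand_contacts(cx$structure, descriptor = cx$descriptor,
                               thresholds = t2)
  expect_true(all(c1$res_key %in% c2$res_key))
  chem1 <- c1$res_key[c1$passes_chemical_filter]
  chem2 <- c2$res_key[c2$passes_chemical_filter]
  expect_true(all(chem1 %in% chem2))
})

test_that("a missing descriptor atom is reported by name", {
  cx <- gen_bundle_complex(35, n_decoys = 2)
  d <- cx$descriptor[cx$descriptor$atom_name != "O1", ]
  expect_error(detect_ligand_contacts(cx$structure, descriptor = d), "O1")
})

test_that("the vdW-sum contact-map rule matches its worked examples", {
  two_ala <- function(cb_dist, tol) {
    lines <- c(
      pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C"),
      pdb_line("ATOM", 2, "CB", "ALA", "A", 1, 1, 0, 0, element = "C"),
      pdb_line("ATOM", 3, "CA", "ALA", "A", 10, cb_dist + 2, 0, 0, element = "C"),
      pdb_line("ATOM", 4, "CB", "ALA", "A", 10, 1 + cb_dist, 0, 0, element = "C"),
      "END"
    )
    build_contact_map(parse_structure(lines),
                      thresholds = contact_thresholds(vdw_tolerance = tol))
  }
  expect_equal(nrow(two_ala(3.2, 0.6)), 1)   # 3.2 < 1.7 + 1.7 + 0.6
  expect_equal(nrow(two_ala(3.5, 0)), 0)     # 0.1 beyond the radius sum
  expect_equal(nrow(two_ala(3.39, 0)), 1)    # just inside, tolerance 0
})

test_that("glycine and sequence neighbours never enter the contact map", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 2, 2, 0, 0, element = "C"),
    pdb_line("ATOM", 3, "CB", "ALA", "A", 2, 3, 0, 0, element = "C"),
    pdb_line("ATOM", 4, "CA", "ALA", "A", 4, 5, 0, 0, element = "C"),
    pdb_line("ATOM", 5, "CB", "ALA", "A", 4, 4, 0, 0, element = "C"),
    "END"
  )
  cm <- build_contact_map(parse_structure(lines))
  expect_equal(nrow(cm), 0)  # CB pair at 1 A but separation 2 < 4
})

test_that("contact maps equal the brute-force oracle on synthetic bundles", {
  for (seed in c(36, 37)) {
    cx <- gen_bundle_complex(seed, n_decoys = 3)
    cm <- build_contact_map(cx$structure)
    expect_equal(map_pair_keys(cm), oracle_contact_map(cx$structure))
  }
})

test_that("contact-map differences are empty for identical maps and swap", {
  sp <- gen_state_pair(38, rewired = rewirable_pairs(38, 2))
  cma <- build_contact_map(sp$active)
  cmi <- build_contact_map(sp$inactive)
  same <- diff_contact_maps(cma, cma, sp$map_active, sp$map_active)
  expect_equal(nrow(same$gained), 0)
  expect_equal(nrow(same$lost), 0)
  d_ab <- diff_contact_maps(cma, cmi, sp$map_active, sp$map_inactive)
  d_ba <- diff_contact_maps(cmi, cma, sp$map_inactive, sp$map_active)
  expect_equal(d_ab$gained, d_ba$lost)
  expect_equal(d_ab$lost, d_ba$gained)
})
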