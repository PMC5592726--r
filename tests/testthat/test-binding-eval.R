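test_that("precision, recall and predictive power match their formulas", {
  expect_equal(precision(c(TP = 3, FP = 1, TN = 0, FN = 0)), 0.75)
  expect_equal(precision(c(TP = 1, FP = 1, TN = 0, FN = 0)), 0.50)
  expect_equal(precision(c(TP = 0, FP = 0, TN = 2, FN = 1)), 0)
  expect_equal(round_metric(recall(c(TP = 2, FP = 0, TN = 0, FN = 1))), 0.67)
  expect_equal(recall(c(TP = 5, FP = 2, TN = 0, FN = 0)), 1)
  expect_equal(recall(c(TP = 0, FP = 0, TN = 0, FN = 3)), 0)
  expect_equal(predictive_power(c(TP = 1, FP = 1, TN = 1, FN = 1)), 50)
  expect_equal(predictive_power(c(TP = 4, FP = 0, TN = 3, FN = 0)), 100)
  expect_error(predictive_power(c(TP = 0, FP = 0, TN = 0, FN = 0)),
               "predictive power")
  expect_error(precision(c(TP = -1, FP = 0, TN = 0, FN = 0)), "non-negative")
})

test_that("round_metric rounds half away from zero", {
  expect_equal(round_metric(0.665), 0.67)
  expect_equal(round_metric(0.675), 0.68)
  expect_equal(round_metric(-0.665), -0.67)
})

test_that("top-half selection keeps residues at or above the midplane", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 5, element = "C"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 2, 0.1, 0, 0, element = "C"),
    pdb_line("ATOM", 3, "CA", "ALA", "A", 3, 0, 0.1, -5, element = "C"),
    "END"
  )
  s <- parse_structure(lines)
  top <- top_half_residues(s, list(axis = c(0, 0, 1), centroid = c(0, 0, 0)))
  expect_setequal(top, c("A:1", "A:2"))  # midpoint tie included

  cx <- gen_bundle_complex(41, n_decoys = 4)
  ax <- bundle_axis(cx$structure)
  got <- top_half_residues(cx$structure, ax)
  ca <- cx$structure$atoms[cx$structure$atoms$name == "CA" &
                             cx$structure$atoms$record_class == "polymer", ]
  proj <- cbind(ca$x, ca$y, ca$z) %*% ax$axis
  want <- ca$res_key[as.vector(proj) >= sum(ax$centroid * ax$axis)]
  expect_setequal(got, want)
})

test_that("evaluation classifies tested residues per the confusion scheme", {
  cx <- gen_bundle_complex(42, n_contacts = c(hbond = 2, salt_bridge = 1,
                                              hydrophobic = 1), n_decoys = 5)
  ct <- detect_ligand_contacts(cx$structure, descriptor = cx$descriptor)
  top <- top_half_residues(cx$structure)

  # every affecting residue contacted, one no-effect residue contacted
  planted <- cx$truth[cx$truth$role == "contact", ]
  decoys <- cx$truth[cx$truth$role == "decoy", ]
  rec <- mutagenesis_records(
    receptor = "toy",
    seqnum = c(planted$seqnum, decoys$seqnum[1:2]),
    mutation = paste0("X", c(planted$seqnum, decoys$seqnum[1:2]), "A"),
    effect = c(rep("affects_response", 3), "no_effect",
               "no_effect", "no_effect")
  )
  ev <- evaluate_complex(ct, rec, top)
  expect_equal(unname(ev$counts),
               c(3, 1, 2, 0))  # TP FP TN FN: one contacted no-effect residue
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 0.75)

  # empty contact list: everything affecting becomes a false negative
  empty <- ct[0, ]
  ev0 <- evaluate_complex(empty, rec, top)
  expect_equal(ev0$counts[["TP"]], 0)
  expect_equal(ev0$counts[["FN"]], 3)
  expect_equal(ev0$recall, 0)
})

test_that("planted confusion matrices are recovered exactly", {
  cx <- gen_bundle_complex(43, n_contacts = c(hbond = 2, salt_bridge = 2,
                                              aromatic_stacking = 1,
                                              hydrophobic = 1), n_decoys = 6)
  ct <- detect_ligand_contacts(cx$structure, descriptor = cx$descriptor)
  top <- top_half_residues(cx$structure)
  for (seed in 1:10) {
    intended <- c(TP = sample(0:4, 1), FP = sample(0:2, 1),
                  TN = sample(0:3, 1), FN = sample(0:3, 1))
    if (sum(intended) == 0) intended["TN"] <- 1
    mt <- gen_mutagenesis_table(cx$truth, intended, seed)
    ev <- evaluate_complex(ct, mt$records, top)
    expect_equal(ev$counts[c("TP", "FP", "TN", "FN")], intended)
  }
})

test_that("untested contacted residues never enter the counts", {
  cx <- gen_bundle_complex(44, n_decoys = 4)
  ct <- detect_ligand_contacts(cx$structure, descriptor = cx$descriptor)
  top <- top_half_residues(cx$structure)
  mt <- gen_mutagenesis_table(cx$truth, c(TP = 2, FP = 1, TN = 1, FN = 1), 7)
  ev_full <- evaluate_complex(ct, mt$records, top)
  # drop one tested contact residue from the records: its contact becomes
  # "untested" and the counts shrink by exactly that residue's cell
  tested_tp <- ev_full$ledger$res_key[ev_full$ledger$outcome == "TP"][1]
  rec2 <- mt$records[mt$records$res_key != tested_tp, ]
  ev2 <- evaluate_complex(ct, rec2, top)
  expect_true(tested_tp %in% ev2$untested_contacts)
  expect_equal(ev2$counts[["TP"]], ev_full$counts[["TP"]] - 1)
  expect_equal(ev2$counts[c("FP", "TN", "FN")],
               ev_full$counts[c("FP", "TN", "FN")])
})

test_that("a residue with mixed mutation outcomes counts as affecting", {
  cx <- gen_bundle_complex(45, n_decoys = 3)
  ct <- detect_ligand_contacts(cx$structure, descriptor = cx$descriptor)
  top <- top_half_residues(cx$structure)
  sn <- cx$truth$seqnum[cx$truth$role == "contact"][1]
  rec <- mutagenesis_records(
    receptor = "toy", seqnum = c(sn, sn),
    mutation = c(paste0("X", sn, "A"), paste0("X", sn, "W")),
    effect = c("no_effect", "affects_response")
  )
  ev <- evaluate_complex(ct, rec, top)
  expect_equal(ev$ledger$effect, "affects_response")
  expect_equal(ev$counts[["TP"]], 1)
})

test_that("records for residues absent from the structure are rejected", {
  cx <- gen_bundle_complex(46, n_decoys = 2)
  ct <- detect_ligand_contacts(cx$structure, descriptor = cx$descriptor)
  rec <- mutagenesis_records("toy", 999, "X999A", "no_effect")
  expect_error(
    evaluate_complex(ct, rec, top_half_residues(cx$structure),
                     known_residues = residues(cx$structure)$res_key),
    "A:999"
  )
})

test_that("EC50 fold changes derive and police the effect class", {
  rec <- mutagenesis_records("toy", c(1, 2), c("A1G", "A2G"),
                             ec50_fold = c(10, 1.2))
  expect_equal(rec$effect, c("affects_response", "no_effect"))
  expect_error(
    mutagenesis_records("toy", 1, "A1G", effect = "no_effect", ec50_fold = 10),
    "inconsistent"
  )
  # threshold is configurable
  rec3 <- mutagenesis_records("toy", 1, "A1G", ec50_fold = 3,
                              fold_threshold = 5)
  expect_equal(rec3$effect, "no_effect")
})

test_that("mutagenesis tables survive a TSV round trip", {
  rec <- mutagenesis_records(
    receptor = c("r1", "r1"), seqnum = c(24, 55),
    generic = c("1.50", "2.50"), mutation = c("N24A", "R55A"),
    effect = c("affects_response", "no_effect"),
    ec50_fold = c(12, NA), source = c("assay", "assay")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutagenesis(rec, path)
  back <- read_mutagenesis(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})

test_that("tidy and glance expose the ledger and the metrics", {
  cx <- gen_bundle_complex(47, n_decoys = 3)
  ct <- detect_ligand_contacts(cx$structure, descriptor = cx$descriptor)
  mt <- gen_mutagenesis_table(cx$truth, c(TP = 2, FP = 1, TN = 1, FN = 0), 3)
  ev <- evaluate_complex(ct, mt$records, top_half_residues(cx$structure))
  expect_s3_class(tidy(ev), "tbl_df")
  g <- glance(ev)
  expect_equal(g$TP, 2)
  expect_equal(g$precision, 2 / 3)
  expect_equal(g$n_tested, 4)
})
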