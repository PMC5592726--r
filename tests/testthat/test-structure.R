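test_that("a minimal PDB parses into one residue with its atoms", {
  s <- parse_structure(c(
    pdb_line("ATOM", 1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 1.4, 0, 0, element = "C"),
    pdb_line("ATOM", 3, "CB", "ALA", "A", 1, 2.0, 1.2, 0, element = "C"),
    "END"
  ))
  expect_equal(nrow(s$atoms), 3)
  rs <- residues(s)
  expect_equal(nrow(rs), 1)
  expect_equal(rs$resname, "ALA")
  expect_equal(s$atoms$is_backbone, c(TRUE, TRUE, FALSE))
})

test_that("altloc handling keeps the highest-occupancy conformer", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.6, altloc = "A",
             element = "C"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 5, 0, 0, occ = 0.4, altloc = "B",
             element = "C"),
    pdb_line("ATOM", 3, "CB", "ALA", "A", 1, 1, 1, 1, element = "C"),
    "END"
  )
  s <- parse_structure(lines)
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$altloc, "A")
  expect_equal(ca$x, 0)
})

test_that("malformed coordinates and empty structures are rejected", {
  bad <- pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C")
  substr(bad, 33, 35) <- "abc"
  expect_error(parse_structure(c(bad, "END")), "malformed coordinate")
  expect_error(parse_structure("END"), "no ATOM/HETATM")
})

test_that("write/parse round trip preserves the synthetic bundle", {
  cx <- gen_bundle_complex(21, n_decoys = 2)
  s2 <- parse_structure(cx$pdb, id = "roundtrip")
  expect_equal(nrow(s2$atoms), nrow(cx$structure$atoms))
  expect_equal(residues(s2)$res_key, residues(cx$structure)$res_key)
  expect_equal(s2$atoms$name, cx$structure$atoms$name)
  expect_lt(max(abs(s2$atoms$x - cx$structure$atoms$x),
                abs(s2$atoms$y - cx$structure$atoms$y),
                abs(s2$atoms$z - cx$structure$atoms$z)), 1e-3)
})

test_that("minimum residue distance matches hand values and the brute oracle", {
  a <- toy_structure(list(CA = c(0, 0, 0)))
  b <- toy_structure(list(CA = c(3, 4, 0)))
  ra <- residue_atoms(a, "A:1")
  rb <- residue_atoms(b, "A:1")
  expect_equal(min_residue_distance(ra, rb), 5)
  expect_equal(min_residue_distance(ra, rb),
               min_residue_distance(rb, ra))
  expect_equal(min_residue_distance(ra, ra), 0)

  set.seed(42)
  for (rep in 1:5) {
    mk <- function(n) {
      nm <- paste0("C", seq_len(n))
      toy_structure(setNames(lapply(seq_len(n), function(i)
        runif(3, -10, 10)), nm))
    }
    s1 <- residue_atoms(mk(10), "A:1")
    s2 <- residue_atoms(mk(10), "A:1")
    expect_equal(min_residue_distance(s1, s2), oracle_min_dist(s1, s2))
  }
})

test_that("empty atom selections are signalled, not returned as distances", {
  gly <- toy_structure(list(N = c(0, 0, 0), CA = c(1.4, 0, 0),
                            C = c(2, 1, 0), O = c(3, 1, 0)), resname = "GLY")
  other <- toy_structure(list(CB = c(9, 9, 9)))
  expect_error(
    min_residue_distance(residue_atoms(gly, "A:1"),
                         residue_atoms(other, "A:1"),
                         atom_filter = "sidechain_only"),
    class = "gpcr_empty_selection"
  )
})

test_that("minimum distance over an atom superset is never larger", {
  s <- toy_structure(list(CB = c(0, 0, 0), CG = c(2, 0, 0), CD1 = c(4, 0, 0),
                          CA = c(-1, 0, 0)), resname = "LEU")
  probe <- toy_structure(list(CB = c(10, 0, 0)))
  all_d <- min_residue_distance(residue_atoms(s, "A:1"),
                                residue_atoms(probe, "A:1"), "all")
  sc_d <- min_residue_distance(residue_atoms(s, "A:1"),
                               residue_atoms(probe, "A:1"), "sidechain_only")
  expect_lte(all_d, sc_d)
})

test_that("bundle axis recovers a line, transforms rigidly, and points up", {
  lines <- purrr::map_chr(1:6, function(i)
    pdb_line("ATOM", i * 2 - 1, "CA", "ALA", "A", i, 0, 0, i * 1.5,
             element = "C"))
  s <- parse_structure(c(lines, "END"))
  ax <- bundle_axis(s)
  expect_equal(abs(ax$axis[3]), 1, tolerance = 1e-9)
  expect_equal(ax$centroid, c(0, 0, mean((1:6) * 1.5)))
  # orientation: first residue is at the bottom here, so axis points down
  expect_lt(ax$axis[3], 0)

  cx <- gen_bundle_complex(22, n_decoys = 2)
  ax1 <- bundle_axis(cx$structure)
  expect_gt(sum(ax1$axis * c(0, 0, 1)), 0.99)
  s2 <- rigid_transform(cx$structure)
  ax2 <- bundle_axis(s2)
  # the axis transforms with the structure: same angle to any pair of atoms
  v1 <- with(cx$structure$atoms[1:2, ], c(diff(x), diff(y), diff(z)))
  v2 <- with(s2$atoms[1:2, ], c(diff(x), diff(y), diff(z)))
  expect_equal(sum(ax1$axis * v1) / sqrt(sum(v1^2)),
               sum(ax2$axis * v2) / sqrt(sum(v2^2)), tolerance = 1e-6)
})
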