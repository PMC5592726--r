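test_that("planted column frequencies are reported exactly", {
  fam <- gen_family_msa(51, 25, profiles = data.frame(
    generic = c("1.50", "2.50"), residue = c("N", "R"),
    frequency = c(23 / 25, 24 / 25)
  ))
  c150 <- conservation_at(fam, "1.50", "N")
  expect_equal(c150$n, 23)
  expect_equal(c150$N, 25)
  expect_equal(c150$percentage, 92)
  expect_equal(conservation_at(fam, "2.50", "R")$percentage, 96)
})

test_that("uniform and empty residue queries hit the boundary values", {
  fam <- gen_family_msa(52, 10)
  cons <- strsplit(default_reference()$sequence, "")[[1]]
  anchor1 <- default_reference()$spans$anchor[1]
  expect_equal(conservation_at(fam, "1.50", cons[anchor1])$percentage, 100)
  expect_equal(conservation_at(fam, "1.50", character())$percentage, 0)
  expect_error(conservation_at(fam, "1.99", "A"), "not mapped")
})

test_that("conservation over a residue partition sums to 100 per column", {
  fam <- gen_family_msa(53, 30, profiles = data.frame(
    generic = c("1.50", "7.52"), residue = c("N", "I"),
    frequency = c(0.8, 0.6)
  ), n_gap_defective = 3)
  alphabet <- c(LETTERS, "-")
  for (pos in c("1.50", "3.50", "7.52")) {
    total <- sum(vapply(setdiff(alphabet, "-"), function(a) {
      conservation_at(fam, pos, a)$percentage
    }, double(1)))
    expect_equal(total, 100, tolerance = 1e-9)
  }
})

test_that("gap rows drop out of the primary denominator but not the other", {
  fam <- gen_family_msa(54, 20, n_gap_defective = 5)
  r <- conservation_at(fam, "1.50", "N")
  expect_equal(r$N, 15)        # 5 rows gapped at helix-1 columns
  expect_equal(r$n_rows, 20)
  expect_equal(r$percentage, 100)
  expect_equal(r$percentage_all, 75)
})

test_that("motif scanning honours alternatives and fails on gaps", {
  ann <- default_reference()
  dry <- motif_spec("TM3_DRY", c("3.49", "3.50", "3.51"), c("DE", "R", "Y"))
  # build three rows around the reference: D..., E..., and a gapped one
  cons <- strsplit(ann$sequence, "")[[1]]
  a3 <- ann$spans$anchor[3]
  mk <- function(ch49, ch50, ch51) {
    s <- cons
    s[a3 - 1] <- ch49; s[a3] <- ch50; s[a3 + 1] <- ch51
    paste(s, collapse = "")
  }
  fam <- aligned_family(
    c("ref", "withD", "withE", "gapped", "wrong"),
    c(paste(cons, collapse = ""), mk("D", "R", "Y"), mk("E", "R", "Y"),
      mk("-", "R", "Y"), mk("A", "R", "Y")),
    ref_id = "ref", annotation = ann
  )
  out <- scan_motif(fam, dry)
  got <- setNames(out$passes$pass, out$passes$id)
  expect_true(got[["withD"]])
  expect_true(got[["withE"]])
  expect_false(got[["gapped"]])
  expect_false(got[["wrong"]])
  expect_equal(out$fraction, 2 / 5)

  # monotone: enlarging an allowed set never turns a pass into a fail
  wider <- motif_spec("TM3_wide", c("3.49", "3.50", "3.51"),
                      c("DEA", "R", "Y"))
  out2 <- scan_motif(fam, wider)
  expect_true(all(out2$passes$pass >= out$passes$pass))
})

test_that("the bitter-taste TM1 motif accepts N1.50 x x I1.53", {
  fam <- gen_family_msa(55, 5)
  tm1 <- builtin_motifs("htas2r")$TM1
  out <- scan_motif(fam, tm1)
  expect_true(all(out$passes$pass))  # consensus carries N1.50 and I1.53
})

test_that("curation discards gap-heavy and motif-less rows with reasons", {
  fam <- gen_family_msa(56, 20, n_gap_defective = 3, n_motif_defective = 2)
  truth <- attr(fam, "truth")
  cur <- curate_family(fam, gap_frac_max = 0.2, required = anchor_motifs())
  expect_equal(nrow(cur$rejected), 5)
  expect_setequal(cur$rejected$id,
                  c(truth$gap_defective, truth$motif_defective))
  expect_equal(length(cur$retained), 15)
  gap_reasons <- cur$rejected$reason[cur$rejected$id %in% truth$gap_defective]
  expect_true(all(grepl("gap fraction", gap_reasons)))
  motif_reasons <- cur$rejected$reason[cur$rejected$id %in% truth$motif_defective]
  expect_true(all(motif_reasons == "missing conserved features"))
})

test_that("curation with no thresholds is the identity", {
  fam <- gen_family_msa(57, 12, n_gap_defective = 2, n_motif_defective = 2)
  cur <- curate_family(fam, gap_frac_max = 1, required = list(),
                       min_motifs = 0)
  expect_equal(length(cur$retained), 12)
  expect_equal(nrow(cur$rejected), 0)
})

test_that("families round-trip through aligned FASTA", {
  fam <- gen_family_msa(58, 8, profiles = data.frame(
    generic = "7.52", residue = "V", frequency = 0.5
  ))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(fam, path)
  back <- read_alignment(path, ref_id = fam$ref_id,
                         annotation = fam$annotation)
  expect_equal(back$rows, fam$rows)
  expect_equal(conservation_at(back, "7.52", "V")$n, 4)
})
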