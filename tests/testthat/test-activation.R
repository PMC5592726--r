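test_that("a single planted rewired pair is reported with support 1", {
  sp <- gen_state_pair(61, rewired = list(c("7.52", "1.53")))
  rep <- aggregate_rewiring(list(sp), min_support = 1)
  expect_equal(nrow(rep$pairs), 1)
  expect_equal(rep$pairs$pos_a, "1.53")
  expect_equal(rep$pairs$pos_b, "7.52")
  expect_equal(rep$pairs$support, 1L)
  expect_equal(rep$pairs$n_gained, 1L)
  expect_setequal(rep$involvement$generic, c("1.53", "7.52"))
})

test_that("identical states and unreachable support give empty reports", {
  sp0 <- gen_state_pair(62, rewired = list())
  rep0 <- aggregate_rewiring(list(sp0), min_support = 1)
  expect_equal(nrow(rep0$pairs), 0)

  sp <- gen_state_pair(63, rewired = rewirable_pairs(63, 2))
  rep <- aggregate_rewiring(list(sp), min_support = 2)
  expect_equal(nrow(rep$pairs), 0)
})

test_that("swapping all state labels preserves the reported pair set", {
  pairs <- purrr::map(64:66, function(s)
    gen_state_pair(s, rewired = rewirable_pairs(s, 2)))
  swapped <- purrr::map(pairs, function(p)
    state_pair(p$receptor, active = p$inactive, inactive = p$active,
               map_active = p$map_inactive, map_inactive = p$map_active))
  r1 <- aggregate_rewiring(pairs, min_support = 1)
  r2 <- aggregate_rewiring(swapped, min_support = 1)
  key <- function(r) paste(r$pairs$pos_a, r$pairs$pos_b, sep = "|")
  expect_setequal(key(r1), key(r2))
  expect_equal(
    dplyr::arrange(r1$pairs, pos_a, pos_b)$n_gained,
    dplyr::arrange(r2$pairs, pos_a, pos_b)$n_lost
  )
})

test_that("lower support thresholds report supersets", {
  shared <- list(c("3.38", "6.38"))
  pairs <- purrr::map(67:69, function(s)
    gen_state_pair(s, rewired = shared))
  extra <- gen_state_pair(70, rewired = c(shared, list(c("1.46", "5.46"))))
  all_pairs <- c(pairs, list(extra))
  r1 <- aggregate_rewiring(all_pairs, min_support = 1)
  r4 <- aggregate_rewiring(all_pairs, min_support = 4)
  key <- function(r) paste(r$pairs$pos_a, r$pairs$pos_b, sep = "|")
  expect_true(all(key(r4) %in% key(r1)))
  expect_equal(key(r4), "3.38|6.38")
  expect_equal(r1$pairs$support[key(r1) == "3.38|6.38"], 4L)
})

test_that("ranking keeps conserved positions ordered by involvement", {
  sp1 <- gen_state_pair(71, rewired = list(c("7.52", "1.53")))
  sp2 <- gen_state_pair(73, rewired = list(c("7.52", "2.56")),
                        receptor = "synthetic2")
  rep <- aggregate_rewiring(list(sp1, sp2), min_support = 1)
  cons <- tibble::tibble(
    generic = c("7.52", "1.53", "2.56"),
    percentage = c(92, 96, 40)
  )
  rk <- rank_activation_positions(rep, cons, min_conservation = 70)
  expect_equal(rk$ranked$generic, c("7.52", "1.53"))
  expect_equal(rk$ranked$count, c(2L, 1L))
  expect_equal(rk$below_threshold$generic, "2.56")

  # a conserved position changing less still outranks a non-conserved one
  expect_false("2.56" %in% rk$ranked$generic)
  expect_error(
    rank_activation_positions(rep, cons[cons$generic != "7.52", ]),
    "7.52"
  )
})

test_that("equal involvement breaks ties by helix then offset", {
  sp <- gen_state_pair(72, rewired = list(c("1.44", "2.56")))
  rep <- aggregate_rewiring(list(sp), min_support = 1)
  cons <- tibble::tibble(generic = c("1.44", "2.56"), percentage = c(90, 90))
  rk <- rank_activation_positions(rep, cons)
  expect_equal(rk$ranked$generic, c("1.44", "2.56"))
})
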