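test_that("scorer matches closed forms on minimal systems", {
  # a single isolated site has no pairs
  expect_identical(score_structure(toy_structure(toy_site(0, 0, 0))), 0)
  # two neutral sites at the pair contact distance sit at -epsilon
  p <- scorer_defaults()
  a <- toy_site(0, 0, 0, lj_r = 1.9, lj_e = 0.08)
  b <- toy_site(3.8, 0, 0, lj_r = 1.9, lj_e = 0.08, strand = "B")
  expect_equal(score_structure(toy_structure(a, b)), -0.08, tolerance = 1e-12)
  # and unlike charges attract on top of it
  qa <- toy_site(0, 0, 0, charge = 1, strand = "A")
  qb <- toy_site(4, 0, 0, charge = -1, strand = "B")
  e <- score_structure(toy_structure(qa, qb))
  expect_lt(e, score_structure(toy_structure(
    toy_site(0, 0, 0), toy_site(4, 0, 0, strand = "B"))))
})

test_that("scorer equals the brute-force pair sum on toy systems", {
  for (seed in 1:6) {
    sites <- random_toy_frame(3 + seed, seed = 100 + seed)
    expect_equal(score_structure(structure(list(sites = sites),
                                           class = "xbeta_structure")),
                 oracle_energy(sites), tolerance = 1e-10)
  }
})

test_that("clashes yield a large finite penalty, never non-finite", {
  s <- toy_structure(toy_site(0, 0, 0), toy_site(0.3, 0, 0, strand = "B"))
  e <- score_structure(s)
  expect_true(is.finite(e))
  expect_gt(e, 500)
})

test_that("scorer is invariant under rigid transforms", {
  sh <- small_sheet()
  e0 <- score_structure(sh)
  rot <- crossbeta:::rot_z(33.3) %*% crossbeta:::rot_x(-71)
  moved <- sh
  moved$sites <- crossbeta:::transform_sites(sh$sites, rot, c(5.1, -2.2, 9.7))
  expect_lt(abs(score_structure(moved) - e0), 1e-6)
})

test_that("per-monomer gain formula follows the reconciled reading", {
  expect_equal(delta_e_per_monomer(4 * -1.9, -1.9, 4), 0)
  expect_equal(delta_e_per_monomer(-2166, -1.9, 4), -539.6, tolerance = 1e-12)
  expect_equal(delta_e_per_monomer(-10, -1, 2), -4)
  # the literal precedence collapses to E_n - E_1
  expect_equal(delta_e_per_monomer(-2166, -1.9, 4, literal = TRUE), -2164.1)
  expect_error(delta_e_per_monomer(-10, -1, 0), ">= 1")
})

test_that("sheet-pairing gain reproduces the published bookkeeping", {
  expect_identical(delta_ep_core(-4211, -2074), -63)
  expect_identical(delta_ep_core(-4300, -2137), -26)
  expect_identical(delta_ep_core(-4307, -2121), -65)
  # one published row disagrees with its own inputs by 1 kcal/mol
  expect_lte(abs(delta_ep_core(-4359, -2166) - (-28)), 1)
  for (x in c(-2074, 0, 13.5)) expect_equal(delta_ep_core(2 * x, x), 0)
  expect_error(delta_ep_core(Inf, -2074), "finite")
})

test_that("ledger averaging reproduces the antiparallel consensus row", {
  ba <- list(energy_ledger(Ep_sheet = -2137, Ep_core = -4300, label = "BAa"),
             energy_ledger(Ep_sheet = -2121, Ep_core = -4307, label = "BA1"),
             energy_ledger(Ep_sheet = -2166, Ep_core = -4359, label = "BA2"))
  avg <- average_ledgers(ba)
  expect_identical(avg$Ep_sheet, -2141)
  expect_identical(avg$Ep_core, -4322)
  expect_identical(avg$dEp_core, -40)
  one <- average_ledgers(ba[1])
  expect_identical(one$Ep_sheet, ba[[1]]$Ep_sheet)
  expect_identical(one$dEp_core, ba[[1]]$dEp_core)
  expect_error(average_ledgers(list()), "at least one")
})

test_that("per-monomer gain stabilizes by the fourth strand", {
  series <- enumerate_assembly_series(beta_monomer(), 5, phase = "BA1")
  led <- assembly_energy_series(series)
  dE <- led$dE_n
  expect_equal(dE[1], 0)
  expect_true(all(diff(dE) < 0))            # gains keep getting more negative
  expect_lt(abs(dE[5] - dE[4]), abs(dE[2] - dE[1]))
})

test_that("ligand classification follows energy competition plus overlap", {
  core <- empty_contact_map(16, LETTERS[1:4], partner = "sheet2")
  core$counts[13, , "hbond"] <- c(40L, 38L, 41L, 39L)
  core$counts[4, "A", "hbond"] <- 10L
  rosm <- empty_contact_map(16, LETTERS[1:4], partner = "rosmarinic-like")
  rosm$counts[13, c("A", "D"), "hbond"] <- c(30L, 25L)
  rosm$counts[3, "A", "hbond"] <- 12L
  resv <- empty_contact_map(16, LETTERS[1:4], partner = "resveratrol-like")
  resv$counts[14, c("A", "D"), "hbond"] <- c(20L, 15L)
  resv$counts[3, "A", "hbond"] <- 10L

  v1 <- classify_ligand(-59, -40, rosm, core)
  expect_identical(v1$call, "inhibitory")
  expect_true(v1$energy_competitive)
  v2 <- classify_ligand(-26, -40, resv, core)
  expect_identical(v2$call, "non-inhibitory")
  expect_lt(v2$overlap, 0.3)
  # boundary: gain equal to the reference, map identical to the core's own
  v3 <- classify_ligand(-40, -40, core, core)
  expect_identical(v3$call, "inhibitory")
  expect_equal(v3$overlap, 1)
  expect_error(classify_ligand(-40, -40, empty_contact_map(8, "A"), core),
               "mismatched")
  # all-zero reference cannot support a call
  blank <- empty_contact_map(16, LETTERS[1:4])
  expect_identical(classify_ligand(-59, -40, rosm, blank)$call, "indeterminate")
})

test_that("making the ligand gain more negative never flips the call off", {
  core <- empty_contact_map(16, LETTERS[1:4])
  core$counts[13, , "hbond"] <- 40L
  lig <- empty_contact_map(16, LETTERS[1:4])
  lig$counts[13, "A", "hbond"] <- 15L
  calls <- vapply(seq(-20, -120, by = -10), function(de)
    classify_ligand(de, -40, lig, core)$call, "")
  first_inh <- match("inhibitory", calls)
  expect_false(is.na(first_inh))
  expect_true(all(calls[first_inh:length(calls)] == "inhibitory"))
})
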