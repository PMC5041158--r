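test_that("hydrogen-bond detection uses a strict distance cutoff", {
  don <- toy_site(0, 0, 0, donor = TRUE, unit = "sheet1")
  acc <- function(x) toy_site(x, 0, 0, acceptor = TRUE, unit = "sheet2")
  expect_identical(nrow(detect_hbonds(rbind(don, acc(2.9)), "sheet1", "sheet2")), 1L)
  expect_identical(nrow(detect_hbonds(rbind(don, acc(3.0)), "sheet1", "sheet2")), 0L)
  # donor-donor pairs are not hydrogen bonds
  dd <- rbind(don, toy_site(2.5, 0, 0, donor = TRUE, unit = "sheet2"))
  expect_identical(nrow(detect_hbonds(dd, "sheet1", "sheet2")), 0L)
  expect_error(detect_hbonds(rbind(don, acc(2.9)), "sheet1", "sheet1"),
               "disjoint")
})

test_that("van der Waals contacts exclude pairs classified as hydrogen bonds", {
  apolar <- rbind(toy_site(0, 0, 0, unit = "sheet1"),
                  toy_site(2.2, 0, 0, unit = "sheet2"))
  expect_identical(nrow(detect_vdw(apolar, "sheet1", "sheet2")), 1L)
  hb_pair <- rbind(toy_site(0, 0, 0, donor = TRUE, unit = "sheet1"),
                   toy_site(2.2, 0, 0, acceptor = TRUE, unit = "sheet2"))
  expect_identical(nrow(detect_vdw(hb_pair, "sheet1", "sheet2")), 0L)
  expect_identical(nrow(detect_hbonds(hb_pair, "sheet1", "sheet2")), 1L)
})

test_that("detection equals the brute-force all-pairs oracle", {
  for (seed in 1:25) {
    sites <- random_toy_frame(20, seed = seed)
    ina <- sites$unit == "sheet1"; inb <- sites$unit == "sheet2"
    ora <- oracle_contacts(sites, ina, inb)
    expect_identical(nrow(detect_hbonds(sites, ina, inb)), ora$hbond)
    expect_identical(nrow(detect_vdw(sites, ina, inb)), ora$vdw)
  }
})

test_that("contact counts are monotone in the cutoff", {
  for (seed in 1:10) {
    sites <- random_toy_frame(24, seed = 200 + seed)
    ina <- sites$unit == "sheet1"; inb <- sites$unit == "sheet2"
    cuts <- c(1.5, 2.3, 3.0, 4.0)
    n_hb <- vapply(cuts, function(ct)
      nrow(detect_hbonds(sites, ina, inb, cutoff = ct)), 0L)
    expect_true(!is.unsorted(n_hb))
  }
})

test_that("frame subsampling keeps floor(n/stride) frames", {
  base <- small_sheet()
  traj <- make_trajectory(trajectory_spec(base, 7, sigma = 0, seed = 1))
  expect_identical(subsample_frames(traj, 3)$n_frames, 2L)
  expect_identical(subsample_frames(traj, 1)$frames, traj$frames)
  expect_error(subsample_frames(traj, 0), ">= 1")
})

test_that("accumulation is linear over identical frames and conserves totals", {
  core <- small_core()
  one <- trajectory(core, list(crossbeta:::coords_of(core$sites)))
  m1 <- accumulate_map(one, "sheet1", "sheet2")
  k <- 4L
  mk <- accumulate_map(trajectory(core, rep(one$frames, k)), "sheet1", "sheet2")
  expect_identical(mk$counts, m1$counts * k)
  expect_identical(mk$frames, k)
  # conservation: totals equal the summed per-frame detections
  fr <- crossbeta:::frame_sites(one, 1)
  per_frame <- nrow(detect_hbonds(fr, "sheet1", "sheet2")) +
    nrow(detect_vdw(fr, "sheet1", "sheet2"))
  expect_identical(sum(m1$counts), as.integer(per_frame))
})

test_that("sheet-sheet contact totals are symmetric between the sheets", {
  traj <- make_trajectory(trajectory_spec(small_core(), 5, sigma = 0.3, seed = 3))
  m12 <- accumulate_map(traj, "sheet1", "sheet2")
  m21 <- accumulate_map(traj, "sheet2", "sheet1")
  expect_identical(sum(m12$counts), sum(m21$counts))
  expect_identical(sum(m12$counts[, , "hbond"]), sum(m21$counts[, , "hbond"]))
})

test_that("an enforced Arg13 ladder dominates the accumulated map", {
  planted <- data.frame(strand = LETTERS[1:4], position = 13,
                        partner = "sheet2", type = "hbond", fraction = 1)
  traj <- make_trajectory(trajectory_spec(small_core(), 20, sigma = 0.3,
                                          planted = planted, seed = 5))
  hb <- accumulate_map(traj, "sheet1", "sheet2", type = "hbond")$counts[, , "hbond"]
  expect_identical(unname(apply(hb, 2, which.max)), rep(13L, 4))
  expect_true(all(hb[13, ] >= 20))
})

test_that("map overlap is a cosine with sane edge cases", {
  m <- empty_contact_map(4, c("A", "B"))
  m$counts[1, "A", "hbond"] <- 3L
  m$counts[2, "B", "vdw"] <- 4L
  expect_equal(map_overlap(m, m), 1.0)
  disj <- empty_contact_map(4, c("A", "B"))
  disj$counts[3, "A", "hbond"] <- 7L
  expect_equal(map_overlap(m, disj), 0.0)
  # hand-computed 4-cell example: cos = (3*1 + 4*2) / (5 * sqrt(5))
  other <- empty_contact_map(4, c("A", "B"))
  other$counts[1, "A", "hbond"] <- 1L
  other$counts[2, "B", "vdw"] <- 2L
  expect_equal(map_overlap(m, other), 11 / (5 * sqrt(5)), tolerance = 1e-12)
  expect_equal(map_overlap(disj, empty_contact_map(4, c("A", "B"))), 0.0)
  expect_error(map_overlap(m, empty_contact_map(5, c("A", "B"))), "mismatched")
})

test_that("a ThT-like ligand forms no hydrogen bonds with the core", {
  sh <- small_sheet()
  docked <- dock_ligand(sh, ligand_pose("ThT-like"), n_poses = 10, seed = 2)
  traj <- make_trajectory(trajectory_spec(docked$complex, 10, sigma = 0.3, seed = 6))
  m <- accumulate_map(traj, list(unit = "sheet1"), "ligand", partner = "ThT-like")
  expect_identical(sum(m$counts[, , "hbond"]), 0L)
})
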