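test_that("beta conformer satisfies its geometric invariants", {
  m <- beta_monomer()
  ca <- m$sites[m$sites$atom == "CA", ]
  expect_identical(nrow(ca), 16L)                 # one CA per residue
  d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_true(all(d > 3.7 & d < 3.9))
  ends <- sqrt(sum((unlist(ca[16, c("x", "y", "z")]) -
                    unlist(ca[1, c("x", "y", "z")]))^2))
  expect_gt(ends, 45)                             # extended chain
  dh <- crossbeta:::backbone_dihedrals(m)
  expect_true(all(abs(dh$phi[-1] - (-139)) < 15))
  expect_true(all(abs(dh$psi[-16] - 135) < 15))
})

test_that("two-residue helix carries the ideal dihedrals exactly", {
  h <- build_monomer("GG", "H")
  dh <- crossbeta:::backbone_dihedrals(h)
  expect_equal(dh$phi[2], -57, tolerance = 1e-8)
  expect_equal(dh$psi[1], -47, tolerance = 1e-8)
})

test_that("builder is deterministic and validates input", {
  a <- build_monomer(PEPT, "B")
  b <- build_monomer(PEPT, "B")
  expect_identical(a$sites, b$sites)              # bit-identical
  expect_error(build_monomer("GXG", "B"), "unknown residue")
  expect_error(build_monomer(PEPT, "N"), "template")
})

test_that("native conformers round-trip through a template file", {
  tmpl <- tempfile(fileext = ".pdb")
  write_structure_pdb(beta_monomer(), tmpl)
  n <- build_monomer(PEPT, "N", template = tmpl)
  expect_identical(n$tag, "N")
  expect_identical(nrow(n$sites[n$sites$atom == "CA", ]), 16L)
  expect_error(build_monomer("GG", "N", template = tmpl), "does not match")
})

test_that("stacking produces the requested strand count and residues", {
  sh1 <- stack_strands(beta_monomer(), 1, phase = "BA1")
  expect_equal(coords_of_sites(sh1$sites), coords_of_sites(beta_monomer()$sites))
  sh4 <- four_sheet()
  expect_identical(length(unique(sh4$sites$strand)), 4L)
  expect_identical(nrow(unique(sh4$sites[, c("strand", "resi")])), 64L)
})

test_that("topology fixes the sign of successive strand axis dot products", {
  m <- beta_monomer()
  bp <- stack_strands(m, 2, phase = "BP")
  ba <- small_sheet()
  ax_bp <- crossbeta:::strand_axes(bp)
  ax_ba <- crossbeta:::strand_axes(ba)
  expect_gt(sum(ax_bp[1, ] * ax_bp[2, ]), 0)
  expect_lt(sum(ax_ba[1, ] * ax_ba[2, ]), 0)
})

test_that("inter-strand spacing stays within 1 A of nominal", {
  for (sh in list(small_sheet(), four_sheet()))
    expect_true(all(abs(crossbeta:::interstrand_ca_spacing(sh) - sh$spacing) < 1))
})

test_that("side-chain phase controls the flip pattern across strands", {
  m <- beta_monomer()
  sc_z <- function(sh, r) {
    s <- sh$sites[sh$sites$atom == "SC" & sh$sites$resi == r, ]
    s$z[order(s$strand)]
  }
  ba1 <- stack_strands(m, 3, phase = "BA1")
  ba2 <- stack_strands(m, 3, phase = "BA2")
  z1 <- sign(sc_z(ba1, 8)); z2 <- sign(sc_z(ba2, 8))
  expect_true(all(z1 == z1[1]))                   # same direction
  expect_true(z2[1] == z2[3] && z2[1] != z2[2])   # alternating
  expect_error(stack_strands(build_monomer(PEPT, "H"), 2, phase = "BP"),
               "incompatible")
})

test_that("BAa search picks a flip combination and respects n <= 6", {
  sh <- stack_strands(beta_monomer(), 2, phase = "BAa")
  expect_identical(length(sh$flips), 2L)
  expect_lte(score_structure(sh),
             score_structure(stack_strands(beta_monomer(), 2, phase = "BA1")) + 1e-6)
  expect_error(stack_strands(beta_monomer(), 7, phase = "BAa"), "n <= 6")
})

test_that("assembly series elements are strand prefixes of each other", {
  series <- enumerate_assembly_series(beta_monomer(), 4, phase = "BA1")
  expect_identical(length(series), 4L)
  for (k in 2:4) {
    prev <- series[[k - 1]]$sites
    cur <- series[[k]]$sites[seq_len(nrow(prev)), ]
    rownames(cur) <- rownames(prev) <- NULL
    expect_identical(cur, prev)
  }
  expect_error(enumerate_assembly_series(beta_monomer(), 1), ">= 2")
})

test_that("backbone hydrogen-bond ladder grows linearly with strand count", {
  m <- beta_monomer()
  # each added strand contributes one inter-strand ladder; antiparallel
  # sheets alternate between their two hydrogen-bond ring types, so the
  # increments sit within +/- 1 of the mean ladder width
  totals <- vapply(1:5, function(n) {
    sh <- stack_strands(m, n, phase = "BA1")
    labs <- LETTERS[seq_len(n)]
    sum(vapply(seq_len(n - 1), function(j)
      nrow(detect_hbonds(sh$sites, labs[j], labs[j + 1])), 0L))
  }, 0L)
  inc <- diff(totals)
  expect_true(all(abs(inc - mean(inc)) <= 1))
  expect_gt(mean(inc), 5)   # a real ladder, not an empty one
})

test_that("pair_sheets returns clash-free poses sorted by energy", {
  sh <- four_sheet()
  cores <- pair_sheets(sh, sh, n_poses = 3, seed = 7)
  expect_gt(length(cores), 0)
  e <- vapply(cores, function(cm) cm$meta$energy, 0)
  expect_true(!is.unsorted(e))
  g <- geometry_defaults()
  for (cm in cores)
    expect_gte(crossbeta:::min_intersheet_distance(cm), g$clash_floor)
  # reproducible for a fixed seed
  cores2 <- pair_sheets(sh, sh, n_poses = 3, seed = 7)
  expect_equal(vapply(cores2, function(cm) cm$meta$energy, 0), e)
  expect_identical(pair_sheets(sh, sh, n_poses = 0, seed = 1), list())
  expect_error(pair_sheets(sh, stack_strands(beta_monomer(), 2, phase = "BA2"),
                           n_poses = 1, seed = 1), "equal strand counts")
})

test_that("structures round-trip through multi-model PDB within format precision", {
  f <- tempfile(fileext = ".pdb")
  for (x in list(beta_monomer(), small_sheet(), small_core())) {
    write_structure_pdb(x, f)
    back <- read_pdb_models(f)
    expect_lt(max(abs(coords_of_sites(back$sites) - coords_of_sites(x$sites))),
              1e-3)
  }
})
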