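# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; no binary fixtures.

PEPT <- "GSTDYGILQINSRWWS"   # HEWL 49-64 with C64S

# Cached builder products (construction is deterministic).
beta_monomer <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_monomer(PEPT, "B")
    m
  }
})

small_sheet <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- stack_strands(beta_monomer(), 2, phase = "BA1")
    s
  }
})

four_sheet <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- stack_strands(beta_monomer(), 4, phase = "BA2")
    s
  }
})

small_core <- local({
  cm <- NULL
  function() {
    if (is.null(cm)) {
      sh <- four_sheet()
      cm <<- pair_sheets(sh, sh, n_poses = 3, seed = 7)[[1]]
    }
    cm
  }
})

coords_of_sites <- function(s) unname(as.matrix(s[, c("x", "y", "z")]))

# A bare interaction site row in the package's site-table layout.
toy_site <- function(x, y, z, lj_r = 1.9, lj_e = 0.08, charge = 0,
                     donor = FALSE, acceptor = FALSE, strand = "A",
                     resi = 1L, atom = "CA", unit = "mono") {
  data.frame(strand = strand, resi = resi, resn = "A", atom = atom,
             elem = "C", heavy = TRUE, donor = donor, acceptor = acceptor,
             aromatic = FALSE, charge = charge, lj_r = lj_r, lj_e = lj_e,
             x = x, y = y, z = z, unit = unit, het = FALSE,
             stringsAsFactors = FALSE)
}

toy_structure <- function(...) {
  sites <- do.call(rbind, list(...))
  structure(list(sites = sites), class = "xbeta_structure")
}

# Independent brute-force energy oracle: explicit double loop over site
# pairs (LJ + screened Coulomb + clash + distance-only hydrogen-bond well
# for donor/acceptor sites). Valid for toy systems without backbone N-H
# geometry (no directional weighting applies there).
oracle_energy <- function(sites, p = scorer_defaults()) {
  n <- nrow(sites)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sites$unit[i] == sites$unit[j] && sites$strand[i] == sites$strand[j] &&
        abs(sites$resi[i] - sites$resi[j]) <= 1) next
    d <- sqrt(sum((sites[i, c("x", "y", "z")] - sites[j, c("x", "y", "z")])^2))
    dc <- max(d, p$clash_floor)
    r0 <- sites$lj_r[i] + sites$lj_r[j]
    eps <- sqrt(sites$lj_e[i] * sites$lj_e[j])
    s6 <- (r0 / dc)^6
    e <- e + eps * (s6^2 - 2 * s6)
    qi <- if (abs(sites$charge[i]) == 1) sites$charge[i] * p$q_scale else sites$charge[i]
    qj <- if (abs(sites$charge[j]) == 1) sites$charge[j] * p$q_scale else sites$charge[j]
    e <- e + p$coulomb_k * qi * qj / (p$diel_slope * dc^2)
    if (d < p$clash_floor) e <- e + p$clash_penalty
    hb_pairs <- (sites$donor[i] && sites$acceptor[j]) +
      (sites$donor[j] && sites$acceptor[i])
    if (hb_pairs > 0 && d < p$hb_max_r)
      e <- e - hb_pairs * p$hb_depth * exp(-((d - p$hb_r0) / p$hb_width)^2)
  }
  e
}

# Independent brute-force contact oracle: all inter-group heavy pairs with
# role filtering; hydrogen bonds take priority over van der Waals.
oracle_contacts <- function(sites, in_a, in_b, hb_cut = 3.0, vdw_cut = 2.3) {
  ia <- which(in_a & sites$heavy)
  ib <- which(in_b & sites$heavy)
  hb <- 0L; vdw <- 0L
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((sites[i, c("x", "y", "z")] - sites[j, c("x", "y", "z")])^2))
    eligible <- (sites$donor[i] && sites$acceptor[j]) ||
      (sites$acceptor[i] && sites$donor[j])
    if (eligible && d < hb_cut) hb <- hb + 1L
    else if (d < vdw_cut && !(eligible && d < hb_cut)) vdw <- vdw + 1L
  }
  list(hbond = hb, vdw = vdw)
}

# Random frames over a small site table, for oracle-equivalence tests.
random_toy_frame <- function(n_atoms, seed, box = 8) {
  set.seed(seed)
  rows <- lapply(seq_len(n_atoms), function(i) {
    grp <- if (i <= n_atoms / 2) "sheet1" else "sheet2"
    kind <- sample(c("plain", "donor", "acceptor", "both"), 1)
    toy_site(runif(1, 0, box), runif(1, 0, box), runif(1, 0, box),
             donor = kind %in% c("donor", "both"),
             acceptor = kind %in% c("acceptor", "both"),
             strand = sample(LETTERS[1:2], 1), resi = sample(1:4, 1),
             atom = "CA", unit = grp)
  })
  do.call(rbind, rows)
}
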