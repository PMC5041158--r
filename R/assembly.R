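# Sheet assembly: stacking monomers into beta-sheets (parallel or
# antiparallel, with controllable side-chain phase) and pairing two sheets
# face to face into a cross-beta core model.

PHASES <- c("BP", "BA1", "BA2", "BAa", "N-stack", "H-stack")

phase_topology <- function(phase) {
  switch(phase, BP = "parallel", BA1 = , BA2 = , BAa = "antiparallel",
         "N-stack" = , "H-stack" = "parallel")
}

phase_tag <- function(phase) {
  switch(phase, BP = , BA1 = , BA2 = , BAa = "B",
         "N-stack" = "N", "H-stack" = "H")
}

# Per-strand rigid placement: optional pi rotation about z (direction
# reversal, antiparallel), optional pi rotation about x (side-chain flip),
# then translation along y to the strand's rank position.
place_strand <- function(sites, rank, spacing, reverse, flip, label) {
  rot <- diag(3)
  if (reverse) rot <- rot_z(180) %*% rot
  if (flip) rot <- rot_x(180) %*% rot
  s <- transform_sites(sites, rot, c(0, (rank - 1) * spacing, 0))
  s$strand <- label
  s
}

strand_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)]
  else paste0(LETTERS[((seq_len(n) - 1) %/% 26)], LETTERS[((seq_len(n) - 1) %% 26) + 1])
}

assemble_sheet <- function(monomer, n, topology, spacing, flips, phase) {
  labels <- strand_labels(n)
  strands <- vector("list", n)
  # registry: one deterministic grid search of the along-strand shift of
  # the second strand against the first (the hydrogen-bond term rewards
  # the canonical N...O ladder); the shift pattern then repeats with the
  # sheet's screw symmetry, so every interface is congruent
  reg <- 0
  if (n > 1) {
    s1 <- place_strand(monomer$sites, 1, spacing,
                       FALSE, flips[1], labels[1])
    s2 <- place_strand(monomer$sites, 2, spacing,
                       topology == "antiparallel", flips[2], labels[2])
    grid <- seq(-3, 3, by = 0.25)
    es <- vapply(grid, function(dx)
      pair_energy(s1, transform_sites(s2, diag(3), c(dx, 0, 0))), 0)
    reg <- grid[which.min(es)]
  }
  for (j in seq_len(n)) {
    reverse <- topology == "antiparallel" && j %% 2 == 0
    shift <- if (topology == "antiparallel") {
      if (j %% 2 == 0) reg else 0
    } else (j - 1) * reg
    s <- place_strand(monomer$sites, j, spacing, reverse, flips[j], labels[j])
    strands[[j]] <- transform_sites(s, diag(3), c(shift, 0, 0))
  }
  sites <- do.call(rbind, strands)
  rownames(sites) <- NULL
  structure(list(seq = monomer$seq, tag = monomer$tag, phase = phase,
                 topology = topology, spacing = spacing, n_strands = n,
                 flips = flips, sites = sites),
            class = c("sheet_assembly", "xbeta_structure"))
}

#' Stack peptide monomers into a beta-sheet assembly
#'
#' Replicates one conformer into `n` strands at the nominal inter-strand
#' spacing. Topology `"antiparallel"` alternates strand directions (strand
#' axis dot products of successive strands are negative); side-chain phase
#' is set by `phase`: `"BA1"` keeps all side chains pointing the same way,
#' `"BA2"` alternates them, `"BP"` is the all-parallel stack, and `"BAa"`
#' searches the side-chain flip combinations exhaustively (n <= 6) for the
#' lowest coarse-score assembly. `"N-stack"`/`"H-stack"` stack native or
#' helical monomers at a wider spacing as energy references.
#'
#' @param monomer A `conformer` whose tag is compatible with `phase`
#'   (`"B"` for BP/BA*, `"H"` for H-stack, `"N"` for N-stack).
#' @param n Number of strands (>= 1).
#' @param topology `"parallel"` or `"antiparallel"`; defaults to the
#'   topology implied by `phase`.
#' @param phase Side-chain phase, one of `"BP"`, `"BA1"`, `"BA2"`,
#'   `"BAa"`, `"N-stack"`, `"H-stack"`.
#' @param spacing Inter-strand spacing in Angstrom; default 4.8 for beta
#'   phases, 10 for N/H stacks.
#' @return A `sheet_assembly`.
#' @examples
#' m <- build_monomer("GSTDYGILQINSRWWS", "B")
#' sh <- stack_strands(m, 4, phase = "BA2")
#' @export
stack_strands <- function(monomer, n, topology = NULL, phase = "BA1",
                          spacing = NULL) {
  if (!inherits(monomer, "conformer")) stop("`monomer` must be a conformer")
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  phase <- match.arg(phase, PHASES)
  if (monomer$tag != phase_tag(phase))
    stop("monomer tag \"", monomer$tag, "\" is incompatible with phase \"",
         phase, "\" (needs \"", phase_tag(phase), "\")")
  if (is.null(topology)) topology <- phase_topology(phase)
  topology <- match.arg(topology, c("parallel", "antiparallel"))
  if (is.null(spacing))
    spacing <- if (phase %in% c("N-stack", "H-stack"))
      geometry_defaults()$stack_spacing else geometry_defaults()$strand_spacing
  flips <- switch(phase,
    BA2 = seq_len(n) %% 2 == 0,
    rep(FALSE, n))
  if (phase == "BAa" && n >= 2) {
    if (n > 6) stop("BAa exhaustive phase search supports n <= 6")
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    best <- NULL; best_e <- Inf
    for (k in seq_len(nrow(combos))) {
      fl <- as.logical(combos[k, ])
      e <- score_structure(assemble_sheet(monomer, n, topology, spacing, fl, phase))
      if (e < best_e - 1e-9) { best_e <- e; best <- fl }
    }
    flips <- best
  }
  assemble_sheet(monomer, n, topology, spacing, flips, phase)
}

#' @export
print.sheet_assembly <- function(x, ...) {
  cat("<sheet_assembly> ", x$n_strands, " strand(s), phase=", x$phase,
      ", ", x$topology, ", spacing=", x$spacing, " A, ",
      length(unique(paste(x$sites$strand, x$sites$resi))), " residues\n", sep = "")
  invisible(x)
}

#' Enumerate a growing series of sheet assemblies
#'
#' Builds the `n_max`-strand assembly once and returns its strand prefixes
#' as assemblies with 1, 2, ..., `n_max` strands, so the series shares one
#' set of geometry parameters and every element's strand coordinates
#' contain the previous element's unchanged. Used for per-monomer
#' energy-gain curves of sheet growth.
#'
#' @inheritParams stack_strands
#' @param n_max Largest strand count (>= 2).
#' @return List of `sheet_assembly` objects with strand counts `1:n_max`.
#' @export
enumerate_assembly_series <- function(monomer, n_max, topology = NULL,
                                      phase = "BA1", spacing = NULL) {
  if (!is.numeric(n_max) || n_max < 2) stop("`n_max` must be >= 2")
  full <- stack_strands(monomer, n_max, topology, phase, spacing)
  labels <- strand_labels(full$n_strands)
  lapply(seq_len(full$n_strands), function(k) {
    s <- full
    s$sites <- full$sites[full$sites$strand %in% labels[seq_len(k)], , drop = FALSE]
    rownames(s$sites) <- NULL
    s$n_strands <- k
    s$flips <- full$flips[seq_len(k)]
    s
  })
}

# Direction of each strand (unit vector CA_1 -> CA_L), for topology checks.
strand_axes <- function(assembly) {
  sites <- assembly$sites
  labs <- unique(sites$strand)
  t(vapply(labs, function(l) {
    ca <- sites[sites$strand == l & sites$atom == "CA", ]
    ca <- ca[order(ca$resi), ]
    unitv(unlist(ca[nrow(ca), c("x", "y", "z")]) - unlist(ca[1, c("x", "y", "z")]))
  }, numeric(3)))
}

# Mean nearest-CA distance between adjacent strands.
interstrand_ca_spacing <- function(assembly) {
  sites <- assembly$sites
  labs <- unique(sites$strand)
  if (length(labs) < 2) return(numeric(0))
  ca <- function(l) coords_of(sites[sites$strand == l & sites$atom == "CA", ])
  vapply(seq_len(length(labs) - 1), function(j) {
    a <- ca(labs[j]); b <- ca(labs[j + 1])
    d <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
    mean(apply(d, 1, min))
  }, 0)
}

combined_core_sites <- function(sheet1, sheet2, ligand = NULL) {
  s1 <- sheet1$sites; s1$unit <- "sheet1"
  s2 <- sheet2$sites; s2$unit <- "sheet2"
  out <- rbind(s1, s2)
  if (!is.null(ligand)) out <- rbind(out, ligand$sites)
  rownames(out) <- NULL
  out
}

new_core_model <- function(sheet1, sheet2, ligand = NULL, meta = list()) {
  structure(list(sheet1 = sheet1, sheet2 = sheet2, ligand = ligand,
                 sites = combined_core_sites(sheet1, sheet2, ligand),
                 meta = meta),
            class = c("core_model", "xbeta_structure"))
}

#' @export
print.core_model <- function(x, ...) {
  cat("<core_model> 2 x ", x$sheet1$n_strands, "-strand sheets",
      if (!is.null(x$ligand)) paste0(" + ligand '", x$ligand$name, "'"),
      if (!is.null(x$meta$energy)) sprintf("  E = %.2f kcal/mol", x$meta$energy),
      "\n", sep = "")
  invisible(x)
}

min_intersheet_distance <- function(core) {
  a <- coords_of(core$sheet1$sites[core$sheet1$sites$heavy, ])
  b <- coords_of(core$sheet2$sites[core$sheet2$sites$heavy, ])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Pair two beta-sheets into candidate cross-beta core models
#'
#' Samples `n_poses` seeded rigid poses of `sheet2` against `sheet1`
#' (180-degree face flip, rotation about the sheet normal with jitter,
#' 1-Angstrom translation grid, separation drawn inside the configured
#' mean-plane window) and refines each by steepest descent on the rigid
#' translation. Clash-containing poses (heavy-atom pair below the clash
#' floor) are discarded; survivors are returned sorted by coarse score,
#' ties broken by generation order.
#'
#' @param sheet1,sheet2 `sheet_assembly` objects with equal strand counts.
#' @param n_poses Number of candidate poses to generate.
#' @param seed Integer seed driving the pose sampling.
#' @return List of `core_model` objects sorted ascending by energy; empty
#'   (with a warning) if no clash-free pose is found.
#' @examples
#' m <- build_monomer("GSTDYGILQINSRWWS", "B")
#' sh <- stack_strands(m, 2, phase = "BA2")
#' cores <- pair_sheets(sh, sh, n_poses = 3, seed = 1)
#' @export
pair_sheets <- function(sheet1, sheet2, n_poses = 10, seed = 1) {
  if (!inherits(sheet1, "sheet_assembly") || !inherits(sheet2, "sheet_assembly"))
    stop("inputs must be sheet_assembly objects")
  if (sheet1$n_strands != sheet2$n_strands)
    stop("sheets must have equal strand counts")
  if (n_poses < 1) return(list())
  g <- geometry_defaults()
  fixed_half <- score_structure(sheet1) + score_structure(sheet2)
  a_sites <- sheet1$sites

  pose_sheet <- function(theta, dx, dy, dz) {
    rot <- rot_z(theta) %*% rot_x(180)   # flip face down, then spin
    transform_sites(sheet2$sites, rot, c(dx, dy, dz))
  }
  pose_energy <- function(theta, dx, dy, dz)
    interaction_energy(a_sites, pose_sheet(theta, dx, dy, dz))

  cores <- with_seed(seed, {
    out <- vector("list", n_poses)
    for (p in seq_len(n_poses)) {
      theta <- sample(c(0, 180), 1) + stats::runif(1, -15, 15)
      dx <- sample(seq(-2, 2, by = 1), 1)
      dy <- sample(seq(-2, 2, by = 1), 1)
      dz <- stats::runif(1, g$sheet_sep_min, g$sheet_sep_max)
      # steepest-descent refinement of the rigid translation
      step <- 0.5
      e <- pose_energy(theta, dx, dy, dz)
      for (it in 1:25) {
        grad <- c(
          pose_energy(theta, dx + 0.05, dy, dz) - pose_energy(theta, dx - 0.05, dy, dz),
          pose_energy(theta, dx, dy + 0.05, dz) - pose_energy(theta, dx, dy - 0.05, dz),
          pose_energy(theta, dx, dy, dz + 0.05) - pose_energy(theta, dx, dy, dz - 0.05)) / 0.1
        gn <- vnorm(grad)
        if (!is.finite(gn) || gn < 1e-6) break
        cand <- c(dx, dy, dz) - step * grad / gn
        cand[3] <- min(max(cand[3], g$sheet_sep_min), g$sheet_sep_max)
        e2 <- pose_energy(theta, cand[1], cand[2], cand[3])
        if (e2 < e - 1e-9) { dx <- cand[1]; dy <- cand[2]; dz <- cand[3]; e <- e2 }
        else { step <- step / 2; if (step < 0.02) break }
      }
      s2 <- sheet2
      s2$sites <- pose_sheet(theta, dx, dy, dz)
      core <- new_core_model(sheet1, s2,
        meta = list(seed = seed, pose = p, theta = theta,
                    translation = c(dx, dy, dz), energy = fixed_half + e))
      if (min_intersheet_distance(core) >= g$clash_floor) out[[p]] <- core
    }
    out
  })
  cores <- Filter(Negate(is.null), cores)
  if (!length(cores)) {
    warning("no clash-free pose found within the search window")
    return(list())
  }
  energies <- vapply(cores, function(cm) cm$meta$energy, 0)
  cores[order(energies)]   # stable sort: ties keep generation order
}
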