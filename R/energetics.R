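# Coarse-grained energy scoring of conformers, sheets and cores, plus the
# energy bookkeeping of sheet growth and sheet pairing and the ligand
# competition classifier. Absolute energies are in kcal/mol on the scale of
# this potential; only bookkeeping identities and orderings are meaningful,
# not agreement with any molecular-mechanics force field.

#' Default parameters of the coarse scorer
#'
#' Lennard-Jones per-role radii and depths are taken from the chemistry
#' table; this list holds the remaining constants: the Coulomb prefactor
#' (kcal mol-1 Ang e-2), the distance-dependent dielectric slope
#' (epsilon(r) = diel_slope * r), the hydrogen-bond well depth (kcal/mol),
#' centre (Ang) and width (Ang), the clash floor (Ang) and its finite
#' penalty (kcal/mol per clashing pair), and the scale applied to formal
#' side-chain charges.
#'
#' @return Named list of scorer constants.
#' @export
scorer_defaults <- function() {
  list(coulomb_k = 332.0637, diel_slope = 4.0,
       hb_depth = 2.5, hb_r0 = 2.9, hb_width = 0.4, hb_max_r = 4.0,
       clash_floor = 2.0, clash_penalty = 1000, q_scale = 0.5)
}

# Cross-distance matrix between two coordinate sets.
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# Attached amide-H coordinates per heavy site (NA rows for non-backbone-N
# donors); used for the directional hydrogen-bond term.
donor_h_coords <- function(sites) {
  out <- matrix(NA_real_, nrow(sites), 3)
  hs <- sites[sites$atom == "H", , drop = FALSE]
  if (!nrow(hs)) return(out)
  key <- paste(sites$unit, sites$strand, sites$resi)
  hkey <- paste(hs$unit, hs$strand, hs$resi)
  idx <- sites$atom == "N"
  m <- match(key[idx], hkey)
  out[idx, ] <- coords_of(hs)[m, , drop = FALSE]
  out
}

# Energy of ordered donor->acceptor hydrogen bonds between site sets.
# Directional for backbone N donors (weight cos^2 of the N-H...A angle at
# H), distance-only for side-chain donors.
hbond_energy <- function(da, db, dmat, p) {
  don <- which(da$sites$donor & da$sites$heavy)
  acc <- which(db$sites$acceptor & db$sites$heavy)
  if (!length(don) || !length(acc)) return(0)
  e <- 0
  bxyz <- coords_of(db$sites)
  axyz <- coords_of(da$sites)
  for (i in don) {
    d <- dmat[i, acc]
    near <- which(d < p$hb_max_r & d > 1e-9)
    if (!length(near)) next
    w <- exp(-((d[near] - p$hb_r0) / p$hb_width)^2)
    h <- da$h[i, ]
    if (!is.na(h[1])) {
      nh <- unitv(h - axyz[i, ])
      ha <- bxyz[acc[near], , drop = FALSE] - matrix(h, length(near), 3, byrow = TRUE)
      ha <- ha / sqrt(rowSums(ha^2))
      cosq <- pmax(0, ha %*% nh)^2
      w <- w * as.vector(cosq)
    }
    if (!is.null(da$mask)) w <- w * da$mask[i, acc][near]
    e <- e - p$hb_depth * sum(w)
  }
  e
}

# Pairwise energy between (or within) site sets. When `b` is NULL the
# intra-set energy is computed over unordered pairs, excluding bonded
# neighbours (same unit & strand, residue separation <= 1).
pair_energy <- function(a, b = NULL, params = scorer_defaults()) {
  p <- params
  intra <- is.null(b)
  if (intra) b <- a
  ha <- a[a$heavy, , drop = FALSE]
  hb <- b[b$heavy, , drop = FALSE]
  if (!nrow(ha) || !nrow(hb)) return(0)
  d <- cross_dist(coords_of(ha), coords_of(hb))
  keep <- matrix(TRUE, nrow(ha), nrow(hb))
  if (intra) {
    keep[lower.tri(keep, diag = TRUE)] <- FALSE
    same <- outer(paste(ha$unit, ha$strand), paste(hb$unit, hb$strand), "==")
    near <- abs(outer(ha$resi, hb$resi, "-")) <= 1
    keep[same & near] <- FALSE
  }
  dc <- pmax(d, p$clash_floor)
  r0 <- outer(ha$lj_r, hb$lj_r, "+")
  eps <- sqrt(outer(ha$lj_e, hb$lj_e))
  s6 <- (r0 / dc)^6
  lj <- eps * (s6^2 - 2 * s6)
  qa <- ifelse(abs(ha$charge) == 1, ha$charge * p$q_scale, ha$charge)
  qb <- ifelse(abs(hb$charge) == 1, hb$charge * p$q_scale, hb$charge)
  coul <- p$coulomb_k * outer(qa, qb) / (p$diel_slope * dc^2)
  clash <- p$clash_penalty * (d < p$clash_floor)
  e <- sum((lj + coul + clash)[keep])
  # hydrogen bonds: ordered donor->acceptor pairs, each counted once.
  if (intra) {
    mask <- keep | t(keep)   # symmetric non-bonded mask, diagonal FALSE
    da <- list(sites = ha, h = donor_h_coords(ha), mask = mask)
    e <- e + hbond_energy(da, list(sites = ha), d, p)
  } else {
    da <- list(sites = ha, h = donor_h_coords(ha))
    db <- list(sites = hb, h = donor_h_coords(hb))
    e <- e + hbond_energy(da, list(sites = hb), d, p)
    e <- e + hbond_energy(db, list(sites = ha), t(d), p)
  }
  e
}

#' Coarse-grained energy of a structure
#'
#' Sums Lennard-Jones, screened Coulomb (distance-dependent dielectric)
#' and directional backbone hydrogen-bond terms over all non-bonded site
#' pairs of a conformer, sheet assembly or core model. Pairs of sites in
#' the same strand separated by one residue or less are excluded as
#' bonded. Site pairs below the clash floor contribute a finite positive
#' penalty; the result is always finite and deterministic.
#'
#' @param structure A `conformer`, `sheet_assembly` or `core_model` (any
#'   object with a `sites` table).
#' @param params Scorer constants, see [scorer_defaults()].
#' @return Energy in kcal/mol.
#' @export
score_structure <- function(structure, params = scorer_defaults()) {
  sites <- if (is.data.frame(structure)) structure else structure$sites
  if (is.null(sites)) stop("`structure` has no site table")
  pair_energy(sites, NULL, params)
}

#' Interaction energy between two site groups
#'
#' Cross-group pairwise energy under the same potential as
#' [score_structure()]; by pairwise additivity,
#' `score(core) = score(sheet1) + score(sheet2) + interaction`.
#'
#' @param a,b Site tables or structures.
#' @param params Scorer constants.
#' @return Energy in kcal/mol.
#' @export
interaction_energy <- function(a, b, params = scorer_defaults()) {
  sa <- if (is.data.frame(a)) a else a$sites
  sb <- if (is.data.frame(b)) b else b$sites
  pair_energy(sa, sb, params)
}
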