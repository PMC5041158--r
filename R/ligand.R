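# Coarse ligand poses: small rigid clusters of interaction sites (H-bond
# donors/acceptors, aromatic/hydrophobic centres) abstracting the docked
# small molecules. Real polyphenol chemistry is not modelled; the site
# vocabulary is what the contact and energy machinery sees.

LIGAND_SITE_ROLES <- c("donor", "acceptor", "aromatic")

ligand_site_row <- function(role, xyz, i) {
  data.frame(
    strand = "L", resi = 1L, resn = "X",
    atom = paste0(switch(role, donor = "D", acceptor = "A", aromatic = "R"), i),
    elem = switch(role, donor = "N", acceptor = "O", aromatic = "C"),
    heavy = TRUE,
    donor = role == "donor", acceptor = role == "acceptor",
    aromatic = role == "aromatic",
    charge = 0,
    lj_r = if (role == "aromatic") 2.2 else 1.7,
    lj_e = if (role == "aromatic") 0.15 else 0.12,
    x = xyz[1], y = xyz[2], z = xyz[3],
    unit = "ligand", het = TRUE, stringsAsFactors = FALSE)
}

#' Create a coarse ligand pose
#'
#' Builds a rigid cluster of interaction sites. The built-in templates
#' encode the qualitative chemistry used throughout: a rosmarinic-like
#' ligand is rich in hydrogen-bond donors and acceptors (catechol
#' hydroxyls and a carboxylate) plus two aromatic centres; a
#' resveratrol-like ligand carries three hydroxyl donors and two aromatic
#' centres; a ThT-like ligand carries aromatic sites only and no
#' hydrogen-bonding capability at all. `"custom"` takes explicit roles
#' and coordinates.
#'
#' @param name One of `"rosmarinic-like"`, `"resveratrol-like"`,
#'   `"ThT-like"`, `"custom"`.
#' @param roles For `"custom"`: character vector of site roles
#'   (`"donor"`, `"acceptor"`, `"aromatic"`).
#' @param coords For `"custom"`: n x 3 coordinate matrix (Angstrom).
#' @return A `ligand_pose`.
#' @examples
#' ligand_pose("rosmarinic-like")
#' @export
ligand_pose <- function(name = c("rosmarinic-like", "resveratrol-like",
                                 "ThT-like", "custom"),
                        roles = NULL, coords = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(roles) || is.null(coords))
      stop("custom ligands need `roles` and `coords`")
    roles <- match.arg(roles, LIGAND_SITE_ROLES, several.ok = TRUE)
    coords <- as.matrix(coords)
    if (nrow(coords) != length(roles) || ncol(coords) != 3)
      stop("`coords` must be length(roles) x 3")
  } else {
    tmpl <- switch(name,
      "rosmarinic-like" = list(
        roles = c("donor", "donor", "acceptor", "acceptor", "donor",
                  "aromatic", "aromatic"),
        coords = rbind(c(0, 0, 0), c(2.8, 0, 0), c(5.6, 0, 0),
                       c(8.4, 0, 0), c(11.2, 0, 0),
                       c(1.4, 2.2, 0), c(9.8, 2.2, 0))),
      "resveratrol-like" = list(
        roles = c("donor", "donor", "donor", "aromatic", "aromatic"),
        coords = rbind(c(0, 0, 0), c(8.8, 1.8, 0), c(8.8, -1.8, 0),
                       c(2.4, 0, 0), c(6.6, 0, 0))),
      "ThT-like" = list(
        roles = c("aromatic", "aromatic", "aromatic"),
        coords = rbind(c(0, 0, 0), c(4.3, 0, 0), c(8.6, 0, 0))))
    roles <- tmpl$roles
    coords <- tmpl$coords
  }
  if (!length(roles)) stop("a ligand needs at least one site")
  rows <- do.call(rbind, lapply(seq_along(roles), function(i)
    ligand_site_row(roles[i], coords[i, ], i)))
  rownames(rows) <- NULL
  structure(list(name = name, sites = rows),
            class = c("ligand_pose", "xbeta_structure"))
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat("<ligand_pose> ", x$name, ": ",
      paste(x$sites$atom, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Place a ligand at a fixed standoff above a sheet face
#'
#' Deterministically centres the ligand over the sheet and offsets it
#' along the face normal. At the default 8 Angstrom standoff the ligand
#' makes no contacts of its own, which makes the placement a clean base
#' for planted-contact trajectories where ground truth must be exactly
#' the planted cells.
#'
#' @param sheet A `sheet_assembly` (or any structure with a site table).
#' @param ligand A `ligand_pose`.
#' @param standoff Distance above the highest heavy atom (Angstrom).
#' @return A list with the placed `ligand_pose` and the `complex`
#'   structure of sheet plus ligand.
#' @export
place_ligand <- function(sheet, ligand, standoff = 8) {
  stopifnot(inherits(ligand, "ligand_pose"))
  sheet_sites <- if (is.data.frame(sheet)) sheet else sheet$sites
  xyz <- coords_of(ligand$sites)
  xyz <- sweep(xyz, 2, colMeans(xyz), "-")
  ctr <- c(mean(range(sheet_sites$x)), mean(range(sheet_sites$y)),
           max(sheet_sites$z[sheet_sites$heavy]) + standoff)
  placed <- ligand
  placed$sites <- set_coords(ligand$sites, sweep(xyz, 2, ctr, "+"))
  complex_sites <- rbind(transform(sheet_sites, unit = "sheet1"),
                         placed$sites)
  rownames(complex_sites) <- NULL
  list(ligand = placed,
       complex = structure(list(sites = complex_sites, ligand = placed),
                           class = "xbeta_structure"))
}

#' Dock a ligand pose onto a sheet face
#'
#' Seeded rigid sampling of the ligand against one face of a sheet
#' assembly (in-plane rotation and translation, height above the
#' side-chain layer), keeping the lowest-energy clash-free placement.
#' A coarse stand-in for small-molecule docking sufficient for the
#' energy-competition and contact-map analyses.
#'
#' @param sheet A `sheet_assembly` (or `core_model`).
#' @param ligand A `ligand_pose`.
#' @param n_poses Number of sampled placements.
#' @param seed Integer seed.
#' @param params Scorer constants.
#' @return A list with the placed `ligand_pose`, its interaction energy
#'   `dE` (kcal/mol) and a `complex` structure of sheet plus ligand.
#' @export
dock_ligand <- function(sheet, ligand, n_poses = 20, seed = 1,
                        params = scorer_defaults()) {
  stopifnot(inherits(ligand, "ligand_pose"))
  sheet_sites <- if (is.data.frame(sheet)) sheet else sheet$sites
  g <- geometry_defaults()
  zmax <- max(sheet_sites$z[sheet_sites$heavy])
  xr <- range(sheet_sites$x); yr <- range(sheet_sites$y)
  lig0 <- ligand$sites
  ctr <- colMeans(coords_of(lig0))
  best <- NULL; best_e <- Inf
  with_seed(seed, {
    for (p in seq_len(n_poses)) {
      theta <- stats::runif(1, 0, 360)
      dx <- stats::runif(1, xr[1], xr[2])
      dy <- stats::runif(1, yr[1], yr[2])
      dz <- zmax + stats::runif(1, 2.5, 4.5)
      s <- transform_sites(lig0, rot_z(theta), c(0, 0, 0))
      xyz <- coords_of(s)
      xyz <- sweep(xyz, 2, colMeans(xyz), "-")
      xyz <- sweep(xyz, 2, c(dx, dy, dz), "+")
      s <- set_coords(s, xyz)
      d <- cross_dist(coords_of(sheet_sites[sheet_sites$heavy, ]), xyz)
      if (min(d) < g$clash_floor) next
      e <- pair_energy(sheet_sites, s, params)
      if (e < best_e) { best_e <- e; best <- s }
    }
  })
  if (is.null(best)) {
    warning("no clash-free ligand placement found")
    return(NULL)
  }
  placed <- ligand
  placed$sites <- best
  complex_sites <- rbind(
    transform(sheet_sites, unit = "sheet1"), best)
  rownames(complex_sites) <- NULL
  list(ligand = placed, dE = best_e,
       complex = structure(list(sites = complex_sites,
                                ligand = placed),
                           class = "xbeta_structure"))
}
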