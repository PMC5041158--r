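# Monomer builder: ideal-geometry peptide conformers at coarse resolution
# (backbone N, CA, C, O, amide H, plus CB and a side-chain centroid site).

# Ideal backbone internal coordinates (Ang / deg).
GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_n_h = 1.010, b_ca_cb = 1.530,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2,
  a_ca_c_o = 120.8, a_c_n_h = 119.5, a_c_ca_cb = 110.5,
  omega = 180)

# Ideal dihedrals per conformation tag: antiparallel beta strand and
# standard alpha helix.
IDEAL_DIHEDRALS <- list(
  B = c(phi = -139, psi = 135),
  H = c(phi = -57,  psi = -47))

#' Default geometry parameters of the builder
#'
#' Nominal inter-strand spacing (4.8 Angstrom, the canonical beta-sheet
#' hydrogen-bond register), the inter-sheet mean-plane separation window
#' (8-12 Angstrom, canonical steric-zipper packing) and the heavy-atom
#' clash floor (2.0 Angstrom).
#'
#' @return Named list of geometry constants.
#' @export
geometry_defaults <- function() {
  list(strand_spacing = 4.8, stack_spacing = 10.0,
       sheet_sep_min = 8.0, sheet_sep_max = 12.0, clash_floor = 2.0)
}

# One row per site of one residue; builds the full site table for a chain.
make_site_rows <- function(res, resi, xyz_list) {
  sc <- SIDECHAIN[res, ]
  atoms <- names(xyz_list)
  n <- length(atoms)
  data.frame(
    strand = rep("A", n), resi = rep(resi, n), resn = rep(res, n),
    atom = atoms,
    elem = vapply(atoms, function(a) switch(a, N = "N", O = "O", H = "H", "C"), ""),
    heavy = atoms != "H",
    donor = vapply(atoms, function(a)
      (a == "N" && res != "P") || (a == "SC" && sc$donor), TRUE),
    acceptor = vapply(atoms, function(a)
      a == "O" || (a == "SC" && sc$acceptor), TRUE),
    aromatic = atoms == "SC" & sc$aromatic,
    charge = vapply(atoms, function(a)
      if (a == "SC") sc$charge else BACKBONE_Q[[a]], 0),
    lj_r = vapply(atoms, function(a)
      if (a == "SC") sc$sc_rad else if (a == "H") 0 else LJ_ROLE[a, "r"], 0),
    lj_e = vapply(atoms, function(a)
      if (a == "SC") (if (sc$aromatic) 0.15 else 0.12)
      else if (a == "H") 0 else LJ_ROLE[a, "e"], 0),
    x = vapply(xyz_list, `[`, 0, 1),
    y = vapply(xyz_list, `[`, 0, 2),
    z = vapply(xyz_list, `[`, 0, 3),
    unit = rep("mono", n), het = rep(FALSE, n),
    stringsAsFactors = FALSE)
}

build_chain_sites <- function(res, phi, psi) {
  L <- length(res)
  g <- GEOM
  N <- CA <- C <- vector("list", L)
  # seed the first residue in a fixed frame
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_n_ca, 0, 0)
  C[[1]] <- place_atom(c(-1, 1, 0), N[[1]], CA[[1]], g$b_ca_c, g$a_n_ca_c, phi[1])
  for (i in 2:L) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]], g$b_c_n, g$a_ca_c_n, psi[i - 1])
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]], g$b_n_ca, g$a_c_n_ca, g$omega)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]], g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  rows <- vector("list", L)
  for (i in seq_len(L)) {
    xyz <- list(N = N[[i]], CA = CA[[i]], C = C[[i]])
    # carbonyl O anti to the next amide N (psi + 180)
    xyz$O <- place_atom(N[[i]], CA[[i]], C[[i]], g$b_c_o, g$a_ca_c_o, psi[i] + 180)
    # amide H trans to the preceding carbonyl O
    if (i > 1) {
      o_prev <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]], g$b_c_o,
                           g$a_ca_c_o, psi[i - 1] + 180)
      xyz$H <- place_atom(o_prev, C[[i - 1]], N[[i]], g$b_n_h, g$a_c_n_h, 180)
    } else {
      xyz$H <- place_atom(C[[1]], CA[[1]], N[[1]], g$b_n_h, 118, 180)
    }
    if (res[i] != "G") {
      cb <- place_atom(N[[i]], C[[i]], CA[[i]], g$b_ca_cb, g$a_c_ca_cb, 122.6)
      xyz$CB <- cb
      d_sc <- SIDECHAIN[res[i], "sc_dist"]
      if (d_sc > 0) xyz$SC <- cb + d_sc * unitv(cb - CA[[i]])
    }
    rows[[i]] <- make_site_rows(res[i], i, xyz)
  }
  do.call(rbind, rows)
}

#' Build an idealized peptide conformer
#'
#' Constructs one peptide monomer from its sequence at ideal backbone
#' geometry. Tag `"B"` gives an extended antiparallel-ideal beta strand
#' (phi = -139, psi = +135), tag `"H"` an alpha helix (phi = -57,
#' psi = -47). Tag `"N"` (native) is template-derived: a multi-model PDB
#' path or structure with matching sequence must be supplied via
#' `template`. Side chains are coarse-grained to Cbeta plus one centroid
#' pseudo-site. The result is deterministic for fixed inputs and is
#' canonicalized with the strand axis along x and side chains along z.
#'
#' @param seq One-letter amino-acid string.
#' @param tag Conformation tag: `"B"` (beta strand), `"H"` (helix) or
#'   `"N"` (native, requires `template`).
#' @param template For `tag = "N"`: path to a PDB file, or a `conformer`,
#'   holding the template coordinates.
#' @return A `conformer` object.
#' @examples
#' m <- build_monomer("GSTDYGILQINSRWWS", "B")
#' @export
build_monomer <- function(seq, tag = c("B", "H", "N"), template = NULL) {
  tag <- match.arg(tag)
  res <- peptide_sequence(seq)
  L <- length(res)
  if (tag == "N") {
    if (is.null(template))
      stop("tag \"N\" requires a template structure (native is template-derived)")
    tmpl <- if (is.character(template)) read_pdb_models(template) else template
    if (inherits(tmpl, "trajectory")) tmpl <- structure_frame(tmpl, 1L)
    sites <- tmpl$sites
    if (max(sites$resi) != L || !identical(sites$resn[match(seq_len(L), sites$resi)], res))
      stop("template sequence does not match `seq`")
    sites$strand <- "A"; sites$unit <- "mono"
  } else {
    d <- IDEAL_DIHEDRALS[[tag]]
    sites <- build_chain_sites(res, rep(d["phi"], L), rep(d["psi"], L))
  }
  sites <- canonicalize_sites(sites)
  rownames(sites) <- NULL
  structure(list(seq = paste(res, collapse = ""), tag = tag, sites = sites),
            class = c("conformer", "xbeta_structure"))
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> ", x$seq, "  tag=", x$tag,
      "  (", nrow(x$sites), " sites)\n", sep = "")
  invisible(x)
}

# Measured backbone dihedrals of a conformer (for checks and tests).
backbone_dihedrals <- function(x) {
  s <- x$sites
  L <- max(s$resi)
  at <- function(i, a) unlist(s[s$resi == i & s$atom == a, c("x", "y", "z")])
  phi <- psi <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1) phi[i] <- torsion_angle(at(i - 1, "C"), at(i, "N"), at(i, "CA"), at(i, "C"))
    if (i < L) psi[i] <- torsion_angle(at(i, "N"), at(i, "CA"), at(i, "C"), at(i + 1, "N"))
  }
  data.frame(resi = seq_len(L), phi = phi, psi = psi)
}
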