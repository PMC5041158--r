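# Trajectory container and contact-map machinery: per-frame hydrogen-bond
# and van der Waals detection at distance cutoffs, accumulation into
# per-strand per-residue maps, frame subsampling and map similarity.

#' Create a trajectory
#'
#' An ordered list of coordinate snapshots over one fixed topology (the
#' site table of a conformer, sheet or core model).
#'
#' @param topology Site table (or structure carrying one) shared by all
#'   frames.
#' @param frames List of n_sites x 3 coordinate matrices.
#' @param meta Optional metadata list (seed, generator spec, ...).
#' @return A `trajectory`.
#' @export
trajectory <- function(topology, frames, meta = list()) {
  sites <- if (is.data.frame(topology)) topology else topology$sites
  if (!length(frames)) stop("a trajectory needs at least one frame")
  nok <- vapply(frames, function(f) is.matrix(f) &&
                  nrow(f) == nrow(sites) && ncol(f) == 3, TRUE)
  if (!all(nok)) stop("all frames must be n_sites x 3 coordinate matrices")
  structure(list(topology = sites, frames = frames,
                 n_frames = length(frames), meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$n_frames, " frame(s), ", nrow(x$topology),
      " sites\n", sep = "")
  invisible(x)
}

# Site table of one frame.
frame_sites <- function(traj, i) set_coords(traj$topology, traj$frames[[i]])

# Single-model structure view of a trajectory frame.
structure_frame <- function(traj, i = 1L) {
  structure(list(sites = frame_sites(traj, i)), class = "xbeta_structure")
}

#' Subsample trajectory frames at a fixed stride
#'
#' Keeps frames at indices `stride, 2*stride, ...`, i.e.
#' `floor(n_frames / stride)` frames.
#'
#' @param traj A `trajectory`.
#' @param stride Positive integer stride.
#' @return A `trajectory` with the subsampled frames.
#' @examples
#' # 200 snapshots at stride 10 -> 20 frames
#' @export
subsample_frames <- function(traj, stride) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(stride) || stride < 1) stop("`stride` must be >= 1")
  stride <- as.integer(stride)
  idx <- seq.int(stride, traj$n_frames, by = stride)
  trajectory(traj$topology, traj$frames[idx],
             meta = c(traj$meta, list(stride = stride)))
}

# Resolve a group selector against a site table into a logical vector.
# Selectors: logical/integer vectors; a unit name ("sheet1", "sheet2",
# "ligand", "mono", "all"); strand labels (e.g. c("A","C") or "A:D").
resolve_group <- function(sites, sel) {
  n <- nrow(sites)
  if (is.logical(sel)) { stopifnot(length(sel) == n); return(sel) }
  if (is.numeric(sel)) return(seq_len(n) %in% sel)
  if (is.list(sel)) {
    keep <- rep(TRUE, n)
    if (!is.null(sel$unit)) keep <- keep & sites$unit %in% sel$unit
    if (!is.null(sel$strands)) keep <- keep & sites$strand %in% sel$strands
    return(keep)
  }
  if (is.character(sel)) {
    if (length(sel) == 1 && sel == "all") return(rep(TRUE, n))
    if (length(sel) == 1 && sel %in% unique(sites$unit))
      return(sites$unit == sel)
    if (length(sel) == 1 && grepl(":", sel)) {
      ab <- strsplit(sel, ":")[[1]]
      sel <- LETTERS[match(ab[1], LETTERS):match(ab[2], LETTERS)]
    }
    return(sites$strand %in% sel)
  }
  stop("cannot interpret group selector")
}

contact_pairs <- function(sites, ga, gb, cutoff, hbond_only,
                          hb_cutoff = NULL) {
  if (any(ga & gb)) stop("groups must be disjoint atom selections")
  ia <- which(ga & sites$heavy)
  ib <- which(gb & sites$heavy)
  empty <- data.frame(a = integer(), b = integer(), dist = numeric(),
                      strand_a = character(), resi_a = integer(),
                      strand_b = character(), resi_b = integer(),
                      type = character(), stringsAsFactors = FALSE)
  if (!length(ia) || !length(ib)) return(empty)
  d <- cross_dist(coords_of(sites[ia, ]), coords_of(sites[ib, ]))
  hb_eligible <- outer(sites$donor[ia], sites$acceptor[ib], "&") |
    outer(sites$acceptor[ia], sites$donor[ib], "&")
  if (hbond_only) {
    hit <- hb_eligible & d < cutoff
    type <- "hbond"
  } else {
    hit <- d < cutoff & !(hb_eligible & d < hb_cutoff)
    type <- "vdw"
  }
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  a <- ia[idx[, 1]]; b <- ib[idx[, 2]]
  data.frame(a = a, b = b, dist = d[idx],
             strand_a = sites$strand[a], resi_a = sites$resi[a],
             strand_b = sites$strand[b], resi_b = sites$resi[b],
             type = type, stringsAsFactors = FALSE)
}

#' Detect hydrogen-bond contacts in one frame
#'
#' One contact per (donor-in-one-group, acceptor-in-the-other) heavy-atom
#' pair at distance strictly below the cutoff. Donor/acceptor roles follow
#' the fixed chemistry table (backbone N donor, backbone O acceptor,
#' side-chain roles per residue; ligand sites carry their declared roles).
#' The criterion is heavy-atom distance only.
#'
#' @param frame Site table (or structure/trajectory-frame view).
#' @param group_a,group_b Disjoint group selectors (see Details in
#'   [accumulate_map()]).
#' @param cutoff Distance cutoff in Angstrom (default 3.0, strict `<`).
#' @return Data frame of contacts (site indices, strands, residues,
#'   distances).
#' @export
detect_hbonds <- function(frame, group_a, group_b, cutoff = 3.0) {
  sites <- if (is.data.frame(frame)) frame else frame$sites
  if (cutoff <= 0) stop("`cutoff` must be positive")
  contact_pairs(sites, resolve_group(sites, group_a),
                resolve_group(sites, group_b), cutoff, hbond_only = TRUE)
}

#' Detect van der Waals contacts in one frame
#'
#' All inter-group heavy-atom pairs at distance strictly below the cutoff,
#' excluding pairs already classified as hydrogen bonds at `hb_cutoff`
#' (hydrogen bonds take priority, so the two classes are disjoint).
#'
#' @inheritParams detect_hbonds
#' @param cutoff van der Waals cutoff in Angstrom (default 2.3, strict).
#' @param hb_cutoff Hydrogen-bond cutoff used for the exclusion rule.
#' @return Data frame of contacts.
#' @export
detect_vdw <- function(frame, group_a, group_b, cutoff = 2.3,
                       hb_cutoff = 3.0) {
  sites <- if (is.data.frame(frame)) frame else frame$sites
  if (cutoff <= 0) stop("`cutoff` must be positive")
  contact_pairs(sites, resolve_group(sites, group_a),
                resolve_group(sites, group_b), cutoff, hbond_only = FALSE,
                hb_cutoff = hb_cutoff)
}

new_contact_map <- function(counts, hb_cutoff, vdw_cutoff, frames, partner) {
  structure(list(counts = counts, hb_cutoff = hb_cutoff,
                 vdw_cutoff = vdw_cutoff, frames = frames,
                 partner = partner),
            class = "contact_map")
}

#' Build an empty contact map
#'
#' @param positions Number of residue positions (peptide length).
#' @param strands Strand labels (e.g. `LETTERS[1:4]`).
#' @param partner Partner descriptor (e.g. `"sheet2"` or a ligand name).
#' @param hb_cutoff,vdw_cutoff Cutoffs recorded in the metadata.
#' @return A `contact_map` of zero counts.
#' @export
empty_contact_map <- function(positions, strands, partner = "partner",
                              hb_cutoff = 3.0, vdw_cutoff = 2.3) {
  counts <- array(0L, dim = c(positions, length(strands), 2),
                  dimnames = list(position = seq_len(positions),
                                  strand = strands,
                                  type = c("hbond", "vdw")))
  new_contact_map(counts, hb_cutoff, vdw_cutoff, 0L, partner)
}

#' @export
print.contact_map <- function(x, ...) {
  tot <- apply(x$counts, 3, sum)
  cat("<contact_map> ", paste(dim(x$counts)[1:2], collapse = " x "),
      " (position x strand), partner=", x$partner,
      ", frames=", x$frames,
      sprintf(", hbond=%d vdw=%d (cutoffs %.1f/%.1f A)\n",
              tot["hbond"], tot["vdw"], x$hb_cutoff, x$vdw_cutoff), sep = "")
  invisible(x)
}

#' Accumulate a contact map over a trajectory
#'
#' Runs [detect_hbonds()] and [detect_vdw()] on every frame and sums the
#' detections into (strand, residue position) cells on `group_a`'s side.
#' Group selectors may be unit names (`"sheet1"`, `"sheet2"`,
#' `"ligand"`), strand label vectors or ranges (`"A:D"`), or logical/index
#' vectors over the topology's sites.
#'
#' @param traj A `trajectory`.
#' @param group_a Selector for the sheet whose (strand, position) cells
#'   index the map.
#' @param group_b Selector for the partner group.
#' @param type `"both"` (default), `"hbond"` or `"vdw"`.
#' @param hb_cutoff,vdw_cutoff Distance cutoffs in Angstrom.
#' @param partner Partner descriptor stored in the metadata; defaults to
#'   a compact rendering of `group_b`.
#' @return A `contact_map`.
#' @export
accumulate_map <- function(traj, group_a = "sheet1", group_b = "sheet2",
                           type = c("both", "hbond", "vdw"),
                           hb_cutoff = 3.0, vdw_cutoff = 2.3,
                           partner = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  type <- match.arg(type)
  if (traj$n_frames < 1) stop("empty trajectory")
  sites <- traj$topology
  ga <- resolve_group(sites, group_a)
  gb <- resolve_group(sites, group_b)
  if (!any(ga) || !any(gb)) stop("empty group selection")
  strands <- sort(unique(sites$strand[ga]))
  L <- max(sites$resi[ga])
  if (is.null(partner))
    partner <- if (is.character(group_b) && length(group_b) == 1)
      group_b else paste(unique(sites$strand[gb]), collapse = "")
  map <- empty_contact_map(L, strands, partner, hb_cutoff, vdw_cutoff)
  for (f in seq_len(traj$n_frames)) {
    fr <- frame_sites(traj, f)
    if (type != "vdw") {
      hb <- detect_hbonds(fr, ga, gb, hb_cutoff)
      if (nrow(hb)) for (k in seq_len(nrow(hb)))
        map$counts[hb$resi_a[k], hb$strand_a[k], "hbond"] <-
          map$counts[hb$resi_a[k], hb$strand_a[k], "hbond"] + 1L
    }
    if (type != "hbond") {
      vw <- detect_vdw(fr, ga, gb, vdw_cutoff, hb_cutoff)
      if (nrow(vw)) for (k in seq_len(nrow(vw)))
        map$counts[vw$resi_a[k], vw$strand_a[k], "vdw"] <-
          map$counts[vw$resi_a[k], vw$strand_a[k], "vdw"] + 1L
    }
  }
  map$frames <- traj$n_frames
  map
}

#' Cosine similarity between two contact maps
#'
#' Cosine of the flattened count vectors; 0 if either map is all-zero.
#'
#' @param map_a,map_b `contact_map` objects over the same index set.
#' @return Similarity in `[0, 1]`.
#' @export
map_overlap <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "contact_map"), inherits(map_b, "contact_map"))
  if (!identical(dim(map_a$counts), dim(map_b$counts)))
    stop("contact maps have mismatched shapes")
  cosine_similarity(as.numeric(map_a$counts), as.numeric(map_b$counts))
}
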