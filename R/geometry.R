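# Internal 3D geometry helpers: internal-to-Cartesian placement (NeRF),
# torsion measurement, rigid transforms and principal-axis canonicalization.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given positions of A, B, C, the bond length |CD|, the bond
# angle B-C-D (deg) and the torsion A-B-C-D (deg). Natural extension
# reference frame construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- deg2rad(angle)
  torsion <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(angle), sin(angle) * cos(torsion), sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Signed torsion angle A-B-C-D in degrees (IUPAC sign convention).
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  -rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# Rotation matrices about coordinate axes (deg).
rot_x <- function(t) { t <- deg2rad(t); matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3) }
rot_y <- function(t) { t <- deg2rad(t); matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3) }
rot_z <- function(t) { t <- deg2rad(t); matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3) }

coords_of <- function(sites) as.matrix(sites[, c("x", "y", "z")])

set_coords <- function(sites, xyz) {
  sites$x <- xyz[, 1]; sites$y <- xyz[, 2]; sites$z <- xyz[, 3]
  sites
}

transform_sites <- function(sites, rot = diag(3), trans = c(0, 0, 0)) {
  xyz <- coords_of(sites) %*% t(rot)
  xyz <- sweep(xyz, 2, trans, "+")
  set_coords(sites, xyz)
}

# Orient a monomer deterministically: backbone principal axis along +x
# (N->C direction positive), second principal direction along y with the
# first backbone O at positive y, z = x cross y. Centroid at origin.
canonicalize_sites <- function(sites) {
  xyz <- coords_of(sites)
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2, ctr, "-")
  bb <- sites$atom %in% c("N", "CA", "C", "O")
  pc <- stats::prcomp(xyz[bb, , drop = FALSE], center = FALSE)
  ax <- pc$rotation[, 1]
  ca <- which(sites$atom == "CA")
  head_tail <- xyz[ca[length(ca)], ] - xyz[ca[1], ]
  if (sum(ax * head_tail) < 0) ax <- -ax
  ay <- pc$rotation[, 2]
  o1 <- xyz[which(sites$atom == "O")[1], ]
  if (sum(ay * o1) < 0) ay <- -ay
  az <- cross3(ax, ay)
  rot <- rbind(ax, ay, az)      # rows are new basis vectors
  set_coords(sites, xyz %*% t(rot))
}

# Evaluate a function with a temporary RNG seed, restoring (or clearing)
# global RNG state afterwards. All package randomness flows through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
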