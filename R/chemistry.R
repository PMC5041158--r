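# Per-residue chemistry tables used by the builder, the scorer and the
# contact detector. Side chains are coarse-grained to Cbeta plus a single
# centroid pseudo-site ("SC") carrying the residue's polarity class.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# Average residue masses (Da); free peptide mass = sum + one water.
RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)

WATER_MASS <- 18.01524

# Side-chain centroid properties: distance from Cbeta along the CA->CB
# direction (Ang), interaction radius (Ang), formal charge class, polarity
# flags for the hydrogen-bond chemistry table, aromatic flag.
SIDECHAIN <- data.frame(
  aa       = AA1,
  sc_dist  = c(0.0, 3.0, 1.2, 1.1, 0.9, 1.9, 1.9, 0.0, 2.2, 1.4,
               1.5, 2.5, 1.9, 2.4, 1.0, 0.8, 0.9, 2.6, 2.8, 1.0),
  sc_rad   = c(1.9, 2.2, 2.0, 1.9, 2.0, 2.1, 2.0, 0.0, 2.2, 2.3,
               2.3, 2.2, 2.3, 2.4, 2.1, 1.8, 2.0, 2.6, 2.4, 2.1),
  charge   = c(0, +1, 0, -1, 0, 0, -1, 0, 0, 0,
               0, +1, 0, 0, 0, 0, 0, 0, 0, 0),
  donor    = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
               FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
  acceptor = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE,
               FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
  aromatic = AA1 %in% c("F", "W", "Y", "H"),
  stringsAsFactors = FALSE)
rownames(SIDECHAIN) <- AA1

# Lennard-Jones site parameters per atom role: radius (Ang, pairwise contact
# distance is r_i + r_j) and well depth (kcal/mol). SC sites take their
# radius from SIDECHAIN and depth 0.12 (0.15 if aromatic).
LJ_ROLE <- data.frame(
  role = c("N", "CA", "C", "O", "CB"),
  r    = c(1.70, 1.90, 1.90, 1.60, 1.90),
  e    = c(0.12, 0.08, 0.08, 0.15, 0.08),
  stringsAsFactors = FALSE)
rownames(LJ_ROLE) <- LJ_ROLE$role

# Small partial charges on the backbone amide dipole; unit charges on
# ionizable side-chain centroids (scaled by the scorer's q_scale).
BACKBONE_Q <- c(N = +0.20, CA = 0, C = 0, O = -0.20, CB = 0, H = 0)

#' Validate a one-letter amino-acid sequence
#'
#' Checks that `seq` is a single string of at least two canonical one-letter
#' residue codes and returns it split into a character vector.
#'
#' @param seq One-letter amino-acid string, e.g. `"GSTDYGILQINSRWWS"`.
#' @return Character vector of validated one-letter codes.
#' @examples
#' peptide_sequence("GSTDYGILQINSRWWS")
#' @export
peptide_sequence <- function(seq) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq))
    stop("`seq` must be a single character string")
  res <- strsplit(toupper(seq), "")[[1]]
  if (length(res) < 2L)
    stop("sequence must contain at least 2 residues")
  bad <- setdiff(res, AA1)
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  res
}

#' Average molecular mass of a free peptide
#'
#' Sum of standard average residue masses plus one water, in Da. Matches
#' synthesis QC values reported by electrospray MS.
#'
#' @param seq One-letter amino-acid string.
#' @return Average mass in Da.
#' @examples
#' peptide_average_mass("GG") # 132.12
#' peptide_average_mass("GSTDYGILQINSRWWS") # ~1883.0
#' @export
peptide_average_mass <- function(seq) {
  if (length(seq) == 1L && nchar(seq) == 1L) {
    # single free amino acid: residue mass + water
    if (!seq %in% AA1) stop("unknown residue code: ", seq)
    return(RESIDUE_MASS[[seq]] + WATER_MASS)
  }
  res <- peptide_sequence(seq)
  sum(RESIDUE_MASS[res]) + WATER_MASS
}
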