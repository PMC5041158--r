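# Synthetic-data generators with known ground truth: jittered multi-frame
# trajectories with planted contacts, noisy kinetic traces, and
# four-component Congo red spectra. These stand in for molecular-dynamics
# and plate-reader output when exercising the counting and fitting
# machinery; they make no physical-realism claims.

#' Specify a synthetic trajectory
#'
#' @param base A `sheet_assembly` or `core_model` providing topology and
#'   reference coordinates.
#' @param n_frames Number of frames.
#' @param sigma Per-coordinate Gaussian jitter in Angstrom (default 0.3:
#'   small enough to preserve hydrogen-bond ladders in most frames, large
#'   enough to vary counts).
#' @param planted Optional data frame with columns `strand`, `position`,
#'   `partner` (`"sheet2"` or `"ligand"`), `type` (`"hbond"`/`"vdw"`) and
#'   `fraction` in `[0, 1]`: each listed contact is enforced in exactly
#'   `floor(fraction * n_frames)` frames.
#' @param seed Mandatory integer seed; recorded in the output metadata.
#' @return A `trajectory_spec`.
#' @export
trajectory_spec <- function(base, n_frames, sigma = 0.3, planted = NULL,
                            seed) {
  if (missing(seed)) stop("`seed` is mandatory in trajectory specs")
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  if (!is.null(planted)) {
    need <- c("strand", "position", "partner", "type", "fraction")
    if (!all(need %in% names(planted)))
      stop("`planted` needs columns: ", paste(need, collapse = ", "))
    if (any(planted$fraction < 0 | planted$fraction > 1))
      stop("planted fractions must be in [0, 1]")
  }
  structure(list(base = base, n_frames = as.integer(n_frames),
                 sigma = sigma, planted = planted, seed = as.integer(seed)),
            class = "trajectory_spec")
}

# Index of the site used as the map-side anchor of a planted contact and
# of the partner atom pulled towards it.
planted_pair_indices <- function(sites, strand, position, partner, type) {
  on_a <- sites$unit %in% c("sheet1", "mono") & sites$strand == strand &
    sites$resi == position
  if (!any(on_a))
    stop("planted contact on non-existent residue: strand ", strand,
         " position ", position)
  if (type == "hbond") {
    a <- which(on_a & sites$donor & sites$heavy)
    if (!length(a)) a <- which(on_a & sites$atom == "N")
    a <- a[length(a)]                      # prefer the side-chain donor
    if (partner == "ligand") {
      b <- which(sites$unit == "ligand" & sites$acceptor)
      if (!length(b)) {
        # donor-only ligand: pair its donor with a residue acceptor instead
        b <- which(sites$unit == "ligand" & sites$donor)
        acc <- which(on_a & sites$acceptor & sites$heavy)
        if (!length(b) || !length(acc))
          stop("ligand has no donor or acceptor site to plant an hbond on")
        a <- acc[length(acc)]              # prefer the side-chain acceptor
      }
    } else {
      b <- which(sites$unit == "sheet2" & sites$strand == strand &
                   sites$resi == position & sites$atom == "O")
      if (!length(b)) b <- which(sites$unit == "sheet2" & sites$atom == "O")
      if (!length(b)) stop("planted partner \"sheet2\" not present in base")
    }
  } else {
    a <- which(on_a & sites$atom == "CA")
    if (partner == "ligand") {
      b <- which(sites$unit == "ligand" & !sites$donor & !sites$acceptor)
      if (!length(b)) b <- which(sites$unit == "ligand")
    } else {
      b <- which(sites$unit == "sheet2" & sites$strand == strand &
                   sites$resi == position & sites$atom == "CA")
      if (!length(b)) b <- which(sites$unit == "sheet2" & sites$atom == "CA")
      if (!length(b)) stop("planted partner \"sheet2\" not present in base")
    }
  }
  c(a = a[1], b = b[1])
}

#' Generate a jittered trajectory with planted contacts
#'
#' Each frame is the base coordinates plus seeded Gaussian jitter. For
#' every planted contact, a seeded choice of exactly
#' `floor(fraction * n_frames)` frames has the partner atom placed just
#' inside the relevant cutoff (2.6 Angstrom for hydrogen bonds, 2.1 for
#' van der Waals) of the map-side site, so the accumulated count in that
#' cell is guaranteed. Deterministic per seed.
#'
#' @param spec A `trajectory_spec`.
#' @return A `trajectory` with the spec echoed in its metadata.
#' @export
make_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  sites <- spec$base$sites
  base_xyz <- coords_of(sites)
  n <- nrow(base_xyz)
  planted <- spec$planted
  pairs <- NULL
  if (!is.null(planted) && nrow(planted)) {
    pairs <- t(vapply(seq_len(nrow(planted)), function(k)
      planted_pair_indices(sites, planted$strand[k], planted$position[k],
                           planted$partner[k], planted$type[k]),
      c(a = 0L, b = 0L)))
  }
  frames <- with_seed(spec$seed, {
    planted_frames <- lapply(seq_len(NROW(pairs)), function(k) {
      m <- floor(planted$fraction[k] * spec$n_frames)
      if (m > 0) sort(sample.int(spec$n_frames, m)) else integer(0)
    })
    lapply(seq_len(spec$n_frames), function(f) {
      xyz <- base_xyz
      if (spec$sigma > 0)
        xyz <- xyz + matrix(stats::rnorm(3 * n, sd = spec$sigma), n, 3)
      for (k in seq_len(NROW(pairs))) {
        if (!(f %in% planted_frames[[k]])) next
        a <- pairs[k, "a"]; b <- pairs[k, "b"]
        target_d <- if (planted$type[k] == "hbond") 2.6 else 2.1
        dir <- xyz[b, ] - xyz[a, ]
        nd <- vnorm(dir)
        u <- if (nd > 1e-9) dir / nd else c(0, 0, 1)
        xyz[b, ] <- xyz[a, ] + target_d * u
      }
      xyz
    })
  })
  trajectory(sites, frames,
             meta = list(seed = spec$seed, sigma = spec$sigma,
                         planted = planted))
}

#' Specify a synthetic kinetic trace
#'
#' @param model `"sigmoid"` or `"exponential"`.
#' @param params Named list of true parameters (`Ai`, `Af`, `t_half`,
#'   `k_agg` for the sigmoid; `A`, `k_agg` for the exponential).
#' @param times Sampling times in hours.
#' @param sigma Gaussian noise s.d. (signal units).
#' @param seed Mandatory integer seed.
#' @return A `trace_spec`.
#' @export
trace_spec <- function(model = c("sigmoid", "exponential"), params, times,
                       sigma = 0, seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("`seed` is mandatory in trace specs")
  need <- if (model == "sigmoid") c("Ai", "Af", "t_half", "k_agg")
          else c("A", "k_agg")
  if (!all(need %in% names(params)))
    stop("params must contain: ", paste(need, collapse = ", "))
  if (params$k_agg <= 0) stop("k_agg must be positive")
  structure(list(model = model, params = params, times = as.numeric(times),
                 sigma = sigma, seed = as.integer(seed)),
            class = "trace_spec")
}

#' Generate a noisy synthetic kinetic trace
#'
#' Evaluates the chosen model at the sampling times and adds seeded
#' Gaussian noise.
#'
#' @param spec A `trace_spec`.
#' @return A `kinetic_trace`.
#' @export
make_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  p <- spec$params
  f <- if (spec$model == "sigmoid")
    sigmoid_model(spec$times, p$Ai, p$Af, p$t_half, p$k_agg)
  else exponential_model(spec$times, p$A, p$k_agg)
  if (spec$sigma > 0)
    f <- f + with_seed(spec$seed, stats::rnorm(length(f), sd = spec$sigma))
  kinetic_trace(spec$times, f, baseline_corrected = TRUE)
}

#' Generate a synthetic Congo red spectrum set
#'
#' Smooth baselines for B (aggregate scattering tail) and C (free-dye
#' absorbance band near 490 nm); D = C + B plus, when `amyloid` is true,
#' a Gaussian peak at `peak_centre`, plus seeded Gaussian noise.
#'
#' @param amyloid Plant the bound-dye difference peak?
#' @param peak_centre Peak position in nm (540 = the amyloid red shift).
#' @param amplitude Peak amplitude (absorbance units).
#' @param sigma Noise s.d. added to D.
#' @param seed Integer seed (required when `sigma > 0`).
#' @param wavelength Grid in nm (default 400-700 by 2).
#' @return A `spectrum_set`.
#' @export
make_cr_spectra <- function(amyloid, peak_centre = 540, amplitude = 0.1,
                            sigma = 0, seed = NULL,
                            wavelength = seq(400, 700, by = 2)) {
  if (min(wavelength) < 400 || max(wavelength) > 700)
    stop("wavelength grid must lie within 400-700 nm")
  w <- wavelength
  B <- 0.05 * exp(-((w - 400) / 120)^2)          # aggregate scattering tail
  C <- 0.60 * exp(-((w - 490) / 35)^2)           # free Congo red band
  D <- B + C
  if (amyloid) D <- D + amplitude * exp(-((w - peak_centre) / 12)^2)
  if (sigma > 0) {
    if (is.null(seed)) stop("`seed` is required when sigma > 0")
    D <- D + with_seed(seed, stats::rnorm(length(w), sd = sigma))
  }
  spectrum_set(w, B, C, D)
}
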