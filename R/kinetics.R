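# Thioflavin-T kinetic traces: normalization, sigmoidal (Boltzmann) and
# mono-exponential aggregation fits, and plateau-based percent inhibition.

#' Create a kinetic trace
#'
#' Time-series ThT fluorescence with strictly increasing time points.
#'
#' @param time Time points in hours, strictly increasing.
#' @param value Fluorescence values (arbitrary units).
#' @param baseline_corrected Whether the dye-only baseline has been
#'   subtracted.
#' @param anchor_time Normalization anchor (h), set by
#'   [normalize_trace()].
#' @return A `kinetic_trace`.
#' @export
kinetic_trace <- function(time, value, baseline_corrected = FALSE,
                          anchor_time = NA_real_) {
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 baseline_corrected = baseline_corrected,
                 anchor_time = anchor_time),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat("<kinetic_trace> ", length(x$time), " points, t = ",
      min(x$time), "..", max(x$time), " h",
      if (!is.na(x$anchor_time)) paste0(", normalized at ", x$anchor_time, " h"),
      "\n", sep = "")
  invisible(x)
}

#' Subtract a dye-only baseline from a trace
#'
#' Subtracts the mean probe-only signal (scalar or per-point vector)
#' before normalization.
#'
#' @param trace A `kinetic_trace`.
#' @param baseline Scalar mean baseline or vector of baseline readings.
#' @return Baseline-corrected `kinetic_trace`.
#' @export
correct_baseline <- function(trace, baseline) {
  stopifnot(inherits(trace, "kinetic_trace"))
  kinetic_trace(trace$time, trace$value - mean(baseline),
                baseline_corrected = TRUE, anchor_time = trace$anchor_time)
}

#' Normalize a trace to its value at an anchor time
#'
#' Divides all values by the value at the sample nearest to
#' `anchor_time` (ties resolved to the earlier point), so the anchor
#' value becomes 1.
#'
#' @param trace A `kinetic_trace`.
#' @param anchor_time Anchor in hours, within the observed time span.
#' @return Normalized `kinetic_trace`.
#' @export
normalize_trace <- function(trace, anchor_time) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (anchor_time < min(trace$time) || anchor_time > max(trace$time))
    stop("anchor time outside the observed time span")
  d <- abs(trace$time - anchor_time)
  i <- which(d == min(d))[1]          # tie -> earlier sample
  ref <- trace$value[i]
  if (ref == 0) stop("anchor value is zero; cannot normalize")
  kinetic_trace(trace$time, trace$value / ref,
                baseline_corrected = trace$baseline_corrected,
                anchor_time = trace$time[i])
}

sigmoid_model <- function(t, Ai, Af, t_half, k_agg)
  Ai + (Af - Ai) / (1 + exp((t_half - t) * k_agg))

exponential_model <- function(t, A, k_agg) A * (1 - exp(-k_agg * t))

fit_start_sigmoid <- function(time, value) {
  lo <- min(value); hi <- max(value); rng <- hi - lo
  half <- lo + rng / 2
  t_half <- time[which(value >= half)[1]]
  if (is.na(t_half)) t_half <- stats::median(time)
  t10 <- time[which(value >= lo + 0.1 * rng)[1]]
  t90 <- time[which(value >= lo + 0.9 * rng)[1]]
  k <- if (!is.na(t10) && !is.na(t90) && t90 > t10) 4 / (t90 - t10) else
    2 / diff(range(time))
  list(Ai = lo, Af = hi, t_half = t_half, k_agg = min(max(k, 1e-4), 10))
}

finish_fit <- function(fit, trace, class_name, par_names) {
  if (inherits(fit, "error")) {
    out <- stats::setNames(as.list(rep(NA_real_, length(par_names))), par_names)
    out$residual_norm <- NA_real_
    out$converged <- FALSE
    out$message <- conditionMessage(fit)
    return(structure(out, class = class_name))
  }
  cf <- as.list(stats::coef(fit))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(par_names)))
  out <- cf[par_names]
  out$residual_norm <- sqrt(sum(stats::resid(fit)^2))
  out$se <- as.list(se)
  out$converged <- TRUE
  out$message <- "converged"
  structure(out, class = class_name)
}

#' Fit the sigmoidal (Boltzmann) aggregation model
#'
#' Least-squares fit of
#' `F(t) = Ai + (Af - Ai) / (1 + exp((t_half - t) * k_agg))` with bounded
#' Levenberg-Marquardt. Starting values: `Ai = min(F)`, `Af = max(F)`,
#' `t_half` at the half-range crossing, `k_agg = 4 / (t90 - t10)`; bound
#' `k_agg` in (0, 10] per hour. Non-convergence is reported in the result
#' (`converged = FALSE`), not thrown.
#'
#' @param trace A (normalized) `kinetic_trace` with >= 5 points.
#' @return A `sigmoid_fit` with `Ai`, `Af`, `t_half`, `k_agg`, residual
#'   norm, standard errors and convergence flag.
#' @export
fit_sigmoid <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (length(trace$time) < 5) stop("need at least 5 points to fit")
  df <- data.frame(t = trace$time, F = trace$value)
  st <- fit_start_sigmoid(df$t, df$F)
  fit <- tryCatch(
    minpack.lm::nlsLM(F ~ Ai + (Af - Ai) / (1 + exp((t_half - t) * k_agg)),
                      data = df, start = st,
                      lower = c(-Inf, -Inf, -Inf, 1e-9),
                      upper = c(Inf, Inf, Inf, 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  finish_fit(fit, trace, "sigmoid_fit", c("Ai", "Af", "t_half", "k_agg"))
}

#' Fit the mono-exponential aggregation model
#'
#' Least-squares fit of `F(t) = A * (1 - exp(-k_agg * t))`, the
#' lag-phase-free kinetics of pre-seeded aggregation.
#'
#' @inheritParams fit_sigmoid
#' @return An `exponential_fit` with `A`, `k_agg`, residual norm and
#'   convergence flag.
#' @export
fit_exponential <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (length(trace$time) < 5) stop("need at least 5 points to fit")
  df <- data.frame(t = trace$time, F = trace$value)
  A0 <- max(df$F)
  i63 <- which(df$F >= 0.632 * A0)[1]
  k0 <- if (!is.na(i63) && df$t[i63] > 0) 1 / df$t[i63] else 0.1
  fit <- tryCatch(
    minpack.lm::nlsLM(F ~ A * (1 - exp(-k_agg * t)), data = df,
                      start = list(A = A0, k_agg = min(max(k0, 1e-4), 10)),
                      lower = c(-Inf, 1e-9), upper = c(Inf, 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  finish_fit(fit, trace, "exponential_fit", c("A", "k_agg"))
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> Ai=%.4g Af=%.4g t_half=%.4g h k_agg=%.4g /h (%s)\n",
              x$Ai, x$Af, x$t_half, x$k_agg, x$message))
  invisible(x)
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("<exponential_fit> A=%.4g k_agg=%.4g /h (%s)\n",
              x$A, x$k_agg, x$message))
  invisible(x)
}

#' Fitted plateau of an aggregation fit
#'
#' `Af` for the sigmoidal model, `A` for the mono-exponential model.
#'
#' @param fit A `sigmoid_fit` or `exponential_fit`.
#' @return Plateau fluorescence.
#' @export
plateau <- function(fit) {
  if (inherits(fit, "sigmoid_fit")) return(fit$Af)
  if (inherits(fit, "exponential_fit")) return(fit$A)
  stop("not an aggregation fit object")
}

#' Percent inhibition from fitted plateaus
#'
#' `100 * (1 - plateau_treated / plateau_control)`: the percent reduction
#' of the ThT plateau relative to the untreated control.
#'
#' @param plateau_treated Fitted plateau with the compound.
#' @param plateau_control Fitted plateau of the untreated control (> 0).
#' @return Percent inhibition.
#' @examples
#' inhibition_percent(0.165, 1.0) # 83.5
#' @export
inhibition_percent <- function(plateau_treated, plateau_control) {
  if (plateau_control <= 0) stop("control plateau must be positive")
  if (plateau_treated < 0) stop("plateaus must be non-negative")
  100 * (1 - plateau_treated / plateau_control)
}
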