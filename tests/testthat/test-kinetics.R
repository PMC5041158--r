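test_that("trace normalization anchors the nearest sample to one", {
  tr <- kinetic_trace(c(0, 10, 20), c(5, 5, 5))
  expect_equal(normalize_trace(tr, 20)$value, c(1, 1, 1))
  # scale invariance
  tr2 <- kinetic_trace(c(0, 10, 20), c(1, 3, 4))
  n1 <- normalize_trace(tr2, 20)
  n2 <- normalize_trace(kinetic_trace(tr2$time, tr2$value * 7.3), 20)
  expect_equal(n1$value, n2$value)
  # anchor midway between two samples resolves to the earlier one
  tr3 <- kinetic_trace(c(0, 10), c(2, 4))
  n3 <- normalize_trace(tr3, 5)
  expect_equal(n3$anchor_time, 0)
  expect_equal(n3$value, c(1, 2))
  expect_error(normalize_trace(kinetic_trace(c(0, 10), c(0, 4)), 0), "zero")
  expect_error(normalize_trace(tr3, 99), "span")
  expect_error(kinetic_trace(c(0, 0, 1), c(1, 2, 3)), "strictly increasing")
})

test_that("noiseless sigmoid traces are recovered to 1e-6 relative", {
  truth <- list(Ai = 0, Af = 1, t_half = 100, k_agg = 0.05)
  tr <- make_trace(trace_spec("sigmoid", truth, seq(0, 300, length.out = 60),
                              sigma = 0, seed = 1))
  fit <- fit_sigmoid(tr)
  expect_true(fit$converged)
  expect_equal(fit$Af, truth$Af, tolerance = 1e-6)
  expect_equal(fit$t_half, truth$t_half, tolerance = 1e-6)
  expect_equal(fit$k_agg, truth$k_agg, tolerance = 1e-6)
  expect_lt(abs(fit$Ai), 1e-6)
  # midpoint identity F(t_half) = (Ai + Af) / 2
  mid <- crossbeta:::sigmoid_model(fit$t_half, fit$Ai, fit$Af, fit$t_half,
                                   fit$k_agg)
  expect_equal(mid, (fit$Ai + fit$Af) / 2, tolerance = 1e-12)
  expect_equal(plateau(fit), fit$Af)
})

test_that("noiseless exponential traces are recovered and start at zero", {
  truth <- list(A = 1, k_agg = 0.2)
  tr <- make_trace(trace_spec("exponential", truth, seq(0, 30, by = 0.5),
                              sigma = 0, seed = 1))
  expect_equal(tr$value[1], 0)            # F(0) = 0 for any parameters
  fit <- fit_exponential(tr)
  expect_true(fit$converged)
  expect_equal(fit$A, truth$A, tolerance = 1e-6)
  expect_equal(fit$k_agg, truth$k_agg, tolerance = 1e-6)
  expect_equal(plateau(fit), fit$A)       # the t -> Inf limit is A
  expect_error(fit_exponential(kinetic_trace(1:3, 1:3)), "5 points")
})

test_that("fit parameters are unbiased over many noisy traces", {
  truth <- list(Ai = 0, Af = 1, t_half = 100, k_agg = 0.05)
  times <- seq(0, 300, length.out = 60)
  n <- 60
  est <- t(vapply(seq_len(n), function(i) {
    tr <- make_trace(trace_spec("sigmoid", truth, times, sigma = 0.05,
                                seed = 1000 + i))
    f <- fit_sigmoid(tr)
    c(f$Ai, f$Af, f$t_half, f$k_agg)
  }, numeric(4)))
  expect_lt(abs(mean(est[, 2]) - truth$Af), 0.05 * truth$Af)
  expect_lt(abs(mean(est[, 3]) - truth$t_half), 0.05 * truth$t_half)
  expect_lt(abs(mean(est[, 4]) - truth$k_agg), 0.05 * truth$k_agg)
  expect_lt(abs(mean(est[, 1])), 0.05)    # Ai truth is 0; 5 % of amplitude
  expect_lt(median(abs(est[, 3] - truth$t_half)), 5)
})

test_that("non-convergence is reported, not thrown", {
  flat <- kinetic_trace(seq(0, 10, by = 1), rep(1, 11))
  fit <- fit_sigmoid(flat)
  expect_true(is.list(fit))
  expect_true(!is.null(fit$converged))
})

test_that("percent inhibition follows the plateau ratio", {
  expect_equal(inhibition_percent(0.165, 1.0), 83.5)
  expect_equal(inhibition_percent(1, 1), 0)
  expect_equal(inhibition_percent(0, 1), 100)
  # invariant under common rescaling of both plateaus
  expect_equal(inhibition_percent(0.165 * 3.7, 1.0 * 3.7),
               inhibition_percent(0.165, 1.0))
  expect_error(inhibition_percent(-0.1, 1), "non-negative")
  expect_error(inhibition_percent(0.5, 0), "positive")
})

test_that("difference spectra make the amyloid call on the 540 nm peak", {
  # D = C + B gives a null difference and a negative call
  null <- make_cr_spectra(amyloid = FALSE, sigma = 0)
  r0 <- cr_difference(null)
  expect_lt(max(abs(r0$R)), 1e-9)
  expect_false(r0$amyloid)
  # a 540 nm peak well above noise is called positive at the right place
  pos <- make_cr_spectra(amyloid = TRUE, peak_centre = 540, amplitude = 0.1,
                         sigma = 0.002, seed = 9)
  rp <- cr_difference(pos)
  expect_true(rp$amyloid)
  expect_lt(abs(rp$peak_wavelength - 540), 10)
  expect_gt(rp$peak_height, rp$noise_floor)
  # the same peak at 480 nm is not an amyloid signature
  off <- make_cr_spectra(amyloid = TRUE, peak_centre = 480, amplitude = 0.1,
                         sigma = 0.002, seed = 9)
  expect_false(cr_difference(off)$amyloid)
  expect_error(spectrum_set(400:410, 1:11, 1:11, 1:10), "grid")
})
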