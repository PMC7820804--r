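# helper: raw-trace construction with a self-consistent bleach profile
# (F0 = (1 - e^-K)/K so the measured post-bleach intensity equals the
# model's immobile reference level)
make_raw_frap <- function(K = 1, tau = 2, mf = 0.8, bleach_at = 21,
                          n = 200, photobleach_rate = 5e-4,
                          noise_sd = 0, seed = NULL) {
  f0 <- (1 - exp(-K)) / K
  tt <- seq_len(n) - 1
  rec <- numeric(n)
  rec[tt < bleach_at] <- 1
  rec[tt >= bleach_at] <- axelrod_recovery(tt[tt >= bleach_at] - bleach_at,
                                           K, tau, mf, f0)
  decay <- exp(-photobleach_rate * tt)
  roi <- 50 + 400 * rec * decay
  if (!is.null(seed)) {
    roi <- withr::with_seed(seed, roi + rnorm(n, sd = noise_sd * 400))
  }
  tibble::tibble(time = tt, roi = roi, background = 50,
                 reference = 50 + 600 * decay)
}

test_that("normalization restores the clean recovery under photobleaching", {
  raw <- make_raw_frap(K = 1, tau = 2, mf = 0.8)
  nt <- normalize_frap(raw, prebleach_frames = 10)
  clean <- axelrod_recovery(nt$time, 1, 2, 0.8, (1 - exp(-1)) / 1)
  expect_lt(max(abs(nt$intensity - clean)), 1e-9)
  expect_equal(attr(nt, "prebleach_intensity"), 1)
})

test_that("a trace without a bleach event is rejected", {
  flat <- tibble::tibble(time = 0:50, roi = rep(300, 51), background = 50,
                         reference = rep(500, 51))
  expect_error(normalize_frap(flat), class = "slb_no_bleach_error")
})

test_that("a decaying reference region is corrected away", {
  decay <- exp(-0.002 * (0:99))
  raw <- tibble::tibble(time = 0:99, roi = 50 + 200 * decay, background = 50,
                        reference = 50 + 200 * decay)
  # after perfect correction the trace is constant, so no bleach is found
  expect_error(normalize_frap(raw), class = "slb_no_bleach_error")
})

test_that("mobile_fraction computes the recovery ratio", {
  expect_equal(as.numeric(mobile_fraction(1.0, 0.2, 0.2)), 0)
  expect_equal(as.numeric(mobile_fraction(1.0, 0.0, 1.0)), 1)
  expect_equal(as.numeric(mobile_fraction(1.0, 0.4, 0.85)), 0.75)
  expect_warning(f <- mobile_fraction(1.0, 0.4, 1.3), "clamped")
  expect_equal(as.numeric(f), 1)
  expect_error(mobile_fraction(0.5, 0.5, 0.7), class = "slb_parameter_error")
})

test_that("beam radius is recovered from a synthetic bleach profile", {
  px <- 0.1; n <- 80
  xs <- matrix(rep(0:(n - 1), each = n), n, n) * px
  ys <- matrix(rep(0:(n - 1), times = n), n, n) * px
  pre <- matrix(1000, n, n)
  post <- 1000 * exp(-1 * exp(-2 * ((xs - 4)^2 + (ys - 4.2)^2) / 1.2^2))
  br <- estimate_beam_radius(pre, post, pixel_size = px)
  expect_equal(br$w, 1.2, tolerance = 1e-3)
  expect_equal(br$bleach_depth, 1, tolerance = 1e-3)
  # unit scaling: doubling the pixel size doubles w
  br2 <- estimate_beam_radius(pre, post, pixel_size = 2 * px)
  expect_equal(br2$w, 2 * br$w, tolerance = 1e-6)
  # no appreciable bleach -> error
  expect_error(estimate_beam_radius(pre, pre * 0.999, pixel_size = px),
               class = "slb_fit_error")
})

test_that("Axelrod fit recovers noiseless parameters to high precision", {
  tr <- simulate_frap_curve(0:180, bleach_depth = 1, tau_d = 2,
                            mobile_fraction = 0.9, f0 = 0.3)
  fit <- fit_axelrod(tr, beam_radius = 1.2)
  expect_equal(fit$bleach_depth, 1, tolerance = 1e-4)
  expect_equal(fit$tau_d, 2, tolerance = 1e-4)
  expect_equal(fit$mobile_fraction, 0.9, tolerance = 1e-4)
  # D = w^2 / (4 tau) by definition
  expect_equal(fit$d_coef, 1.2^2 / (4 * fit$tau_d), tolerance = 1e-12)
  # fitted asymptote consistent with the mobile-fraction formula
  mf_check <- mobile_fraction(1, fit$f0, fit$f_inf)
  expect_lt(abs(as.numeric(mf_check) - fit$mobile_fraction), 0.02)
})

test_that("fitted recovery is monotone over the data range", {
  tr <- simulate_frap_curve(0:180, 1.2, 3, 0.85, 0.3, noise_sd = 0.02,
                            seed = 12)
  fit <- fit_axelrod(tr, beam_radius = 1)
  curve <- axelrod_recovery(tr$time, fit$bleach_depth, fit$tau_d,
                            fit$mobile_fraction, fit$f0)
  expect_true(all(diff(curve) >= -1e-12))
})

test_that("forward/inverse roundtrip stays accurate under noise", {
  w <- 1.0; tau <- 2; d_true <- w^2 / (4 * tau); mf_true <- 0.9
  errs_d <- errs_mf <- numeric(20)
  for (s in 1:20) {
    tr <- simulate_frap_curve(0:180, 1, tau, mf_true, 0.3, noise_sd = 0.01,
                              seed = 500 + s)
    fit <- fit_axelrod(tr, beam_radius = w)
    errs_d[s] <- abs(fit$d_coef - d_true) / d_true
    errs_mf[s] <- abs(fit$mobile_fraction - mf_true)
  }
  expect_lt(median(errs_d), 0.05)
  expect_lt(median(errs_mf), 0.03)
})
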