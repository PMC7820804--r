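test_that("track-length filter keeps exactly tracks longer than five frames", {
  t5 <- manual_track(1, x = 1:5 / 10, y = rep(0, 5))
  t6 <- manual_track(2, x = 1:6 / 10, y = rep(0, 6))
  t9 <- manual_track(3, x = 1:9 / 10, y = rep(0, 9))
  tracks <- dplyr::bind_rows(t5, t6, t9)
  kept <- filter_tracks(tracks, min_length = 6)
  expect_setequal(unique(kept$particle_id), c(2, 3))
  expect_warning(filter_tracks(t5, min_length = 6), "removed")
  empty <- tracks[0, ]
  expect_equal(nrow(filter_tracks(empty)), 0)
})

test_that("a single two-frame track gives MSD(1) = d^2", {
  tr <- manual_track(1, x = c(0, 0.3), y = c(0, 0.4))  # d = 0.5
  msd <- compute_ensemble_msd(tr, frame_interval = 0.01, max_lag = 1)
  expect_equal(msd$msd, 0.25)
  expect_equal(msd$n_obs, 1L)
})

test_that("ensemble MSD pools overlapping windows over all tracks", {
  # two tracks with constant velocity: displacements are exact multiples
  tr <- dplyr::bind_rows(
    manual_track(1, x = 0.1 * (0:4), y = rep(0, 5)),
    manual_track(2, x = rep(0, 5), y = 0.2 * (0:4)))
  msd <- compute_ensemble_msd(tr, frame_interval = 0.01, max_lag = 2)
  # lag 1: four 0.1^2 and four 0.2^2 displacements
  expect_equal(msd$msd[1], mean(c(rep(0.01, 4), rep(0.04, 4))))
  expect_equal(msd$n_obs, c(8L, 6L))
})

test_that("MSD is invariant under time reversal of every track", {
  trk <- simulate_tracks(30, 10, 0.5, frame_interval = 0.01, seed = 6)
  rev <- trk |>
    dplyr::group_by(particle_id) |>
    dplyr::mutate(x = rev(x), y = rev(y)) |>
    dplyr::ungroup()
  m1 <- compute_ensemble_msd(trk, 0.01, max_lag = 5)
  m2 <- compute_ensemble_msd(rev, 0.01, max_lag = 5)
  expect_equal(m1$msd, m2$msd, tolerance = 1e-12)
})

test_that("fit_msd recovers an exact line", {
  lag_time <- (1:6) * 0.01
  curve <- tibble::tibble(lag = 1:6, lag_time = lag_time,
                          msd = 4 * 2.0 * lag_time, sem = 0.001, n_obs = 100L)
  class(curve) <- c("msd_curve", class(curve))
  fit <- fit_msd(curve, n_points = 5, exposure_time = 0)
  expect_equal(fit$d_coef, 2.0, tolerance = 1e-12)
  expect_equal(fit$sigma_loc, 0, tolerance = 1e-9)
})

test_that("fit_msd decomposes a constant MSD into sigma only", {
  curve <- tibble::tibble(lag = 1:5, lag_time = (1:5) * 0.01,
                          msd = rep(0.01, 5), sem = 0.001, n_obs = 100L)
  class(curve) <- c("msd_curve", class(curve))
  fit <- fit_msd(curve, n_points = 5, exposure_time = 0)
  expect_equal(fit$d_coef, 0, tolerance = 1e-12)
  expect_equal(fit$sigma_loc, 0.05, tolerance = 1e-9)
})

test_that("the exposure term shifts the offset, not the slope", {
  # MSD generated with the full model: 4 D t + 4 s^2 - (4/3) D tE
  d_true <- 1.2; s_true <- 0.04; te <- 0.01
  lag_time <- (1:5) * 0.01
  curve <- tibble::tibble(lag = 1:5, lag_time = lag_time,
                          msd = 4 * d_true * lag_time + 4 * s_true^2 -
                            (4 / 3) * d_true * te,
                          sem = 0.001, n_obs = 100L)
  class(curve) <- c("msd_curve", class(curve))
  fit <- fit_msd(curve, n_points = 5, exposure_time = te)
  expect_equal(fit$d_coef, d_true, tolerance = 1e-10)
  expect_equal(fit$sigma_loc, s_true, tolerance = 1e-8)
  # the lag reading of the same printed formula collapses to (8/3) D t
  curve2 <- curve
  curve2$msd <- (8 / 3) * d_true * lag_time + 4 * s_true^2
  fit2 <- fit_msd(curve2, n_points = 5, blur_model = "lag")
  expect_equal(fit2$d_coef, d_true, tolerance = 1e-10)
})

test_that("negative fitted offsets are clamped and flagged", {
  lag_time <- (1:5) * 0.01
  curve <- tibble::tibble(lag = 1:5, lag_time = lag_time,
                          msd = 4 * 1 * lag_time - 0.004, sem = 0.001,
                          n_obs = 100L)
  class(curve) <- c("msd_curve", class(curve))
  fit <- fit_msd(curve, n_points = 5, exposure_time = 0)
  expect_equal(fit$sigma_loc, 0)
  expect_true("negative_sigma_sq_clamped" %in% fit$flags)
})

test_that("MSD fitting is unbiased over seeded replicates", {
  d_true <- 0.8; s_true <- 0.04
  ests <- vapply(1:20, function(s) {
    trk <- simulate_tracks(120, 15, d_true, sigma_loc = s_true,
                           frame_interval = 0.01, seed = 100 + s)
    fit <- fit_msd(compute_ensemble_msd(trk, 0.01, max_lag = 5),
                   n_points = 5, exposure_time = 0)
    fit$d_coef
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - d_true), 3 * se)
})

test_that("pipeline equivalence: imaging then tracking reproduces track MSD", {
  trk <- make_grid_tracks(n_side = 3, track_length = 12, d_coef = 0.08,
                          frame_interval = 0.02, seed = 2)
  stk <- render_image_stack(trk, image_size = c(70, 70), pixel_size = 0.1,
                            psf_sigma = 1.2, photons_per_spot = 2000,
                            background_level = 5, offset = "none",
                            noise = "none")
  loc <- detect_particles_stack(stk, min_intensity = 20,
                                psf_sigma_guess = 1.2)
  tl <- filter_tracks(link_tracks(loc, max_displacement = 0.5,
                                  pixel_size = 0.1, frame_interval = 0.02))
  m_img <- compute_ensemble_msd(tl, 0.02, max_lag = 4)
  m_true <- compute_ensemble_msd(trk, 0.02, max_lag = 4)
  expect_true(all(abs(m_img$msd / m_true$msd - 1) < 0.02))
})
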