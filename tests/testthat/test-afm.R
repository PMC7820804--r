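test_that("the contact point is located within one sampling step", {
  fc <- simulate_force_curve(4590, indenter = sphere_indenter(18.5),
                             contact_point_um = 1.2, z_range_um = 3,
                             sampling_step_nm = 2)
  cp <- find_contact_point(fc)
  expect_lt(abs(as.numeric(cp) - 1.2), 0.002)
  # adding a constant force offset does not move the contact point
  fc2 <- dplyr::mutate(fc, force_nn = force_nn + 3)
  cp2 <- find_contact_point(fc2)
  expect_lt(abs(as.numeric(cp2) - as.numeric(cp)), 0.002)
  # all-zero force: no contact
  flat <- tibble::tibble(z_um = seq(0, 2, by = 0.002), force_nn = 0)
  expect_error(find_contact_point(flat), class = "slb_no_contact_error")
})

test_that("Hertz fitting recovers the modulus from a noiseless curve", {
  fc <- simulate_force_curve(4590, indenter = sphere_indenter(18.5),
                             contact_point_um = 1, z_range_um = 3,
                             sampling_step_nm = 2)
  fit <- fit_hertz(fc, radius_um = 18.5)
  expect_lt(abs(fit$young_modulus - 4590) / 4590, 0.01)
  expect_lt(abs(fit$contact_point - 1), 0.01)
})

test_that("Hertz fitting is invariant to a constant force offset", {
  fc <- simulate_force_curve(4590, indenter = sphere_indenter(18.5),
                             contact_point_um = 1, z_range_um = 3,
                             sampling_step_nm = 2, noise_sd_nn = 0.2,
                             seed = 21)
  f1 <- fit_hertz(fc, radius_um = 18.5)
  f2 <- fit_hertz(dplyr::mutate(fc, force_nn = force_nn + 2.5),
                  radius_um = 18.5)
  expect_equal(f2$young_modulus, f1$young_modulus, tolerance = 0.01)
})

test_that("zero-force curves are rejected by the Hertz fit", {
  flat <- tibble::tibble(z_um = seq(0, 2, by = 0.002), force_nn = 0)
  expect_error(fit_hertz(flat, radius_um = 18.5),
               class = "slb_no_contact_error")
})

test_that("modulus recovery over 16 noisy curves is accurate and tight", {
  ests <- vapply(1:16, function(s) {
    fc <- simulate_force_curve(4590, indenter = sphere_indenter(18.5),
                               contact_point_um = 1, z_range_um = 3,
                               sampling_step_nm = 2, noise_sd_nn = 1,
                               seed = 700 + s)
    fit_hertz(fc, radius_um = 18.5)$young_modulus
  }, numeric(1))
  expect_lt(abs(mean(ests) - 4590) / 4590, 0.05)
  expect_lt(sd(ests) / mean(ests), 0.10)
})

test_that("smooth curves yield no push-through events", {
  # noiseless
  fc <- make_smooth_curve(noise_sd_nn = 0)
  expect_equal(nrow(detect_push_through(fc)), 0)
  # noisy, over many seeds (false-positive control)
  fp <- sum(vapply(1:50, function(s) {
    nrow(detect_push_through(make_smooth_curve(seed = 800 + s)))
  }, numeric(1)))
  expect_equal(fp, 0)
})

test_that("a bilayer-thickness breakthrough is measured accurately", {
  fc <- make_pushthrough_curve(z_jump_nm = 3.9, breakthrough_force_nn = 5,
                               seed = 31)
  ev <- detect_push_through(fc)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$z_jump_nm - 3.9), 0.5)        # within one sampling step
  expect_lt(abs(ev$breakthrough_force_nn - 5), 0.1)
  # detection rate across seeds
  hits <- vapply(1:50, function(s) {
    nrow(detect_push_through(make_pushthrough_curve(seed = 900 + s)))
  }, numeric(1))
  expect_gte(sum(hits == 1), 49)
})

test_that("the z-jump estimate is unbiased within one sampling step", {
  jumps <- vapply(1:20, function(s) {
    ev <- detect_push_through(make_pushthrough_curve(seed = 950 + s))
    if (nrow(ev) == 1) ev$z_jump_nm else NA_real_
  }, numeric(1))
  expect_lt(abs(mean(jumps, na.rm = TRUE) - 3.9), 0.5)
})

test_that("two stacked bilayers give two sequential events", {
  fc <- make_pushthrough_curve(z_jump_nm = c(3.9, 3.9),
                               breakthrough_force_nn = c(4, 7), seed = 41)
  ev <- detect_push_through(fc)
  expect_equal(nrow(ev), 2)
  expect_true(all(diff(ev$z_start_um) > 0))
  expect_lt(max(abs(ev$z_jump_nm - 3.9)), 1)
})

test_that("slope ratios behave as expected", {
  expect_equal(slope_ratio(list(slope_before = 2, slope_after = 4)), 0.5)
  expect_error(slope_ratio(list(slope_before = 2, slope_after = 0)),
               class = "slb_degenerate_error")
  # matched substrate stiffness before and after: ratio near 1 (noiseless)
  fc <- make_pushthrough_curve(z_jump_nm = 3.9, breakthrough_force_nn = 5,
                               noise_sd_nn = 0)
  ev <- detect_push_through(fc)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(slope_ratio(ev) - 1), 0.1)
})
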