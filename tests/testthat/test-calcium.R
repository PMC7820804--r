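test_that("a flat noisy trace yields no peaks", {
  set.seed(1)
  tr <- tibble::tibble(cell_id = 1, time = 0:199,
                       intensity = 100 + rnorm(200, sd = 1))
  expect_equal(nrow(detect_peaks(tr)), 0)
})

test_that("inserted transients are detected at their times and heights", {
  times <- 0:299
  y <- rep(100, 300)
  for (ctr in c(60, 150, 240)) {
    y <- y + 100 * 4 * exp(-(times - ctr)^2 / (2 * 8^2))
  }
  tr <- tibble::tibble(cell_id = 1, time = times, intensity = y)
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 3)
  expect_true(all(abs(sort(pk$time) - c(60, 150, 240)) <= 1))
  # baseline 100, peak max 500 -> height multiple 5
  expect_equal(pk$height_multiple, rep(5, 3), tolerance = 1e-6)
  expect_true(all(pk$integrated_intensity > 0))
})

test_that("baseline-relative metrics are scale invariant", {
  pop <- simulate_calcium_population(20, responder_fraction = 0.6, seed = 5)
  scaled <- dplyr::mutate(pop, intensity = intensity * 7.3)
  p1 <- detect_peaks(pop)
  p2 <- detect_peaks(scaled)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p1$height_multiple, p2$height_multiple, tolerance = 1e-9)
  s1 <- summarize_population(summarize_cells(pop, p1))
  s2 <- summarize_population(summarize_cells(scaled, p2))
  expect_equal(s1$fraction_responding, s2$fraction_responding)
  expect_equal(s1$fraction_multipeak_of_responders,
               s2$fraction_multipeak_of_responders)
})

test_that("peak count is non-increasing in the prominence threshold", {
  pop <- simulate_calcium_population(30, responder_fraction = 0.8,
                                     multipeak_fraction = 0.5, seed = 6)
  counts <- vapply(c(0.25, 0.5, 1, 2, 4), function(pr) {
    nrow(detect_peaks(pop, min_prominence_multiple = pr))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-cell summaries implement the response definitions", {
  tr <- tibble::tibble(cell_id = rep(1:3, each = 100),
                       time = rep(0:99, 3),
                       intensity = 100)
  peaks <- tibble::tibble(
    cell_id = c(2, 3, 3),
    time = c(30, 20, 60),
    height_multiple = c(4, 3, 5),
    prominence = c(300, 200, 400),
    integrated_intensity = c(1000, 800, 1200),
    baseline = 100)
  cs <- summarize_cells(tr, peaks)
  expect_equal(cs$responding, c(FALSE, TRUE, TRUE))
  expect_equal(cs$multipeak, c(FALSE, FALSE, TRUE))
  expect_equal(cs$time_to_first_peak, c(NA, 30, 20))
  ps <- summarize_population(cs)
  expect_equal(ps$fraction_responding, 2 / 3)
  expect_equal(ps$fraction_multipeak_of_responders, 1 / 2)
  expect_equal(ps$mean_time_to_first_peak, 25)
})

test_that("multipeak fraction is missing (not zero) with no responders", {
  tr <- tibble::tibble(cell_id = 1:4, time = 0, intensity = 100)
  cs <- summarize_cells(tr, detect_peaks(
    tibble::tibble(cell_id = 1, time = 0:20, intensity = 100 + 0.01 * (0:20))))
  ps <- summarize_population(cs)
  expect_equal(ps$fraction_responding, 0)
  expect_true(is.na(ps$fraction_multipeak_of_responders))
})

test_that("traces are extracted from rendered stacks (bright static disk)", {
  tr_in <- tibble::tibble(cell_id = 1, time = 0:19, intensity = 200)
  stk <- render_calcium_stack(tr_in, image_size = c(48, 48), cell_radius = 5,
                              background_level = 10, noise_sd = 0)
  tr <- extract_traces(stk, min_cell_area = 20, frame_interval = 1)
  expect_equal(length(unique(tr$cell_id)), 1)
  expect_equal(nrow(tr), 20)
  # constant disk -> constant trace near the disk level (segmentation may
  # include some blurred rim pixels, diluting the mean slightly)
  expect_lt(diff(range(tr$intensity)), 1e-6)
  expect_gt(mean(tr$intensity), 150)
  expect_lte(mean(tr$intensity), 200 + 1e-6)
})

test_that("a brightening cell shows its step; empty stacks warn", {
  tr_in <- dplyr::bind_rows(
    tibble::tibble(cell_id = 1, time = 0:19, intensity = 200),
    tibble::tibble(cell_id = 2, time = 0:19,
                   intensity = c(rep(200, 10), rep(600, 10))))
  stk <- render_calcium_stack(tr_in, image_size = c(64, 64), cell_radius = 5,
                              background_level = 10, noise_sd = 0)
  tr <- extract_traces(stk, min_cell_area = 20, frame_interval = 1)
  expect_equal(length(unique(tr$cell_id)), 2)
  rng <- tr |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(spread = max(intensity) - min(intensity))
  # one flat trace, one with a clear step
  expect_equal(sum(rng$spread < 50), 1)
  expect_equal(sum(rng$spread > 200), 1)
  expect_warning(empty <- extract_traces(array(10, dim = c(16, 16, 3))),
                 "No cells")
  expect_equal(nrow(empty), 0)
})

test_that("population fractions are recovered from simulated traces", {
  pop <- simulate_calcium_population(200, responder_fraction = 0.7,
                                     multipeak_fraction = 0.3, seed = 7)
  gt <- ground_truth(pop)$cells
  ps <- summarize_population(summarize_cells(pop, detect_peaks(pop)))
  se_resp <- sqrt(0.7 * 0.3 / 200)
  expect_lt(abs(ps$fraction_responding - mean(gt$responder)), 3 * se_resp)
  n_resp <- sum(gt$responder)
  se_multi <- sqrt(0.3 * 0.7 / n_resp)
  expect_lt(abs(ps$fraction_multipeak_of_responders -
                  mean(gt$multipeak[gt$responder])), 3 * se_multi)
})

test_that("end-to-end: rendered movie reproduces ground-truth fractions", {
  pop <- simulate_calcium_population(16, responder_fraction = 0.6,
                                     multipeak_fraction = 0.4,
                                     duration = 240, seed = 8)
  gt <- ground_truth(pop)$cells
  stk <- render_calcium_stack(pop, image_size = c(96, 96), cell_radius = 5,
                              background_level = 10, noise_sd = 1, seed = 9)
  tr <- extract_traces(stk, min_cell_area = 20, frame_interval = 1)
  expect_equal(length(unique(tr$cell_id)), 16)
  ps <- summarize_population(summarize_cells(tr, detect_peaks(tr)))
  expect_lt(abs(ps$fraction_responding - mean(gt$responder)),
            3 * sqrt(0.6 * 0.4 / 16))
})
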