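test_that("average_stack is the pixel-wise mean", {
  a <- matrix(1:6, 2, 3); b <- matrix(7:12, 2, 3)
  stk <- array(c(a, b), dim = c(2, 3, 2))
  expect_equal(average_stack(stk), (a + b) / 2)
  expect_equal(average_stack(array(a, dim = c(2, 3, 1))), a)
  expect_equal(average_stack(a), a)  # single frame passes through
  expect_error(average_stack(array(0, dim = c(2, 3, 0))),
               class = "slb_input_error")
})

test_that("rolling-ball background removes a constant exactly", {
  img <- matrix(7, 30, 30)
  expect_equal(rolling_ball_background(img, radius = 5),
               matrix(0, 30, 30))
  expect_error(rolling_ball_background(img, radius = 20),
               class = "slb_parameter_error")
})

test_that("rolling-ball background matches a brute-force opening", {
  set.seed(2)
  base <- outer(seq(0, 5, length.out = 24), seq(0, 3, length.out = 24), "+")
  img <- base
  img[8, 8] <- img[8, 8] + 50   # narrow spot
  bg <- rolling_ball_background(img, radius = 4, return_background = TRUE)
  brush <- EBImage::makeBrush(9, shape = "disc")
  oracle <- opening_brute_force(img, 4, brush = brush)
  expect_equal(bg, oracle, tolerance = 1e-9)
})

test_that("spots on a smooth ramp keep their amplitude", {
  ramp <- outer(seq(10, 40, length.out = 60), seq(5, 20, length.out = 60), "+")
  img <- ramp
  spots <- rbind(c(15, 20), c(40, 45))
  for (k in seq_len(nrow(spots))) {
    img[spots[k, 1] + (-1:1), spots[k, 2] + (-1:1)] <-
      img[spots[k, 1] + (-1:1), spots[k, 2] + (-1:1)] + 30
  }
  out <- rolling_ball_background(img, radius = 10)
  for (k in seq_len(nrow(spots))) {
    expect_lt(abs(out[spots[k, 1], spots[k, 2]] - 30) / 30, 0.05)
  }
  # the ramp itself is removed away from the spots (interior region)
  expect_lt(max(out[25:35, 25:35]), 1)
})

test_that("Otsu threshold matches exhaustive between-class-variance search", {
  cases <- list(
    withr::with_seed(3, c(rnorm(400, 30, 6), rnorm(300, 80, 10))),
    withr::with_seed(4, rexp(600, 1 / 40)),
    withr::with_seed(5, runif(512, 0, 100))
  )
  for (v in cases) {
    expect_equal(as.numeric(otsu_threshold(v)), otsu_brute_force(v),
                 tolerance = 1e-12)
  }
})

test_that("Otsu handles two-valued and constant images", {
  img <- matrix(rep(c(0, 100), each = 50), 10, 10)
  m <- otsu_mask(img)
  expect_true(all(m == (img == 100)))
  expect_error(otsu_threshold(matrix(5, 4, 4)),
               class = "slb_degenerate_error")
})

test_that("exclusion hits the trivial extremes", {
  # probe uniform over the cell: no depletion
  ci <- simulate_contact_image(depletion_factor = 1)
  ex <- compute_exclusion(ci)
  expect_equal(ex$exclusion, 0, tolerance = 1e-9)
  # probe absent from the contact: full exclusion
  ci0 <- simulate_contact_image(depletion_factor = 0)
  expect_equal(compute_exclusion(ci0)$exclusion, 1, tolerance = 1e-9)
})

test_that("a 0.5 depletion factor is measured within mask-edge tolerance", {
  ci <- simulate_contact_image(depletion_factor = 0.5)
  ex <- compute_exclusion(ci)
  expect_lt(abs(ex$exclusion - 0.5), 0.05)
  expect_true(all(ex$cell_mask[ex$contact_mask]))   # contact within cell
})

test_that("exclusion is invariant under intensity scaling", {
  ci <- simulate_contact_image(depletion_factor = 0.4, noise_sd = 2,
                               seed = 11)
  e1 <- compute_exclusion(ci$channel_contact, ci$channel_probe)
  e2 <- compute_exclusion(3.7 * ci$channel_contact, 3.7 * ci$channel_probe)
  expect_equal(e1$exclusion, e2$exclusion, tolerance = 1e-9)
})

test_that("exclusion increases as the depletion factor decreases", {
  ex <- vapply(c(1, 0.75, 0.5, 0.25, 0), function(f) {
    compute_exclusion(simulate_contact_image(depletion_factor = f))$exclusion
  }, numeric(1))
  expect_true(all(diff(ex) > 0))
  expect_true(all(ex <= 1))
})

test_that("degenerate exclusion inputs raise errors", {
  ci <- simulate_contact_image()
  expect_error(compute_exclusion(ci$channel_contact,
                                 ci$channel_probe[1:10, 1:10]),
               class = "slb_input_error")
  # probe zero everywhere outside: mean_out = 0
  probe <- matrix(0, 128, 128)
  probe[ci$contact_mask] <- 5
  expect_error(compute_exclusion(ci$channel_contact, probe),
               class = "slb_degenerate_error")
})
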