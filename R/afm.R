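# AFM force-curve analysis: Hertz modulus and bilayer push-through detection.
# Curves are approach segments: tibble(z_um, force_nn), z increasing toward
# the sample.

check_force_curve <- function(curve) {
  if (!all(c("z_um", "force_nn") %in% names(curve))) {
    abort("A force curve needs columns `z_um` and `force_nn`.",
          class = "slb_input_error")
  }
  if (any(diff(curve$z_um) <= 0)) {
    abort("`z_um` must be strictly increasing over the approach segment.",
          class = "slb_input_error")
  }
  if (any(!is.finite(curve$force_nn))) {
    abort("Forces must be finite.", class = "slb_input_error")
  }
  invisible(curve)
}

#' Locate the tip-sample contact point
#'
#' Fits the baseline (mean and noise sd) on the leading `baseline_fraction` of
#' the curve, takes the first sustained excursion above
#' `baseline + 3 * noise sd` as a coarse contact estimate, then refines it by
#' a grid/golden-section search of the contact point that minimizes the
#' residual of a Hertz-type power-law fit just past contact.
#'
#' @param curve Force-curve tibble (`z_um`, `force_nn`).
#' @param baseline_fraction Fraction of points (from the start) assumed to be
#'   pre-contact (default 0.3).
#' @param exponent Contact-law exponent used for refinement: 1.5 for a
#'   spherical indenter (default), 2 for a pyramid.
#' @return Contact point, um, with attributes `baseline` (nN) and `noise_sd`
#'   (nN).
#' @export
find_contact_point <- function(curve, baseline_fraction = 0.3,
                               exponent = 1.5) {
  check_force_curve(curve)
  n <- nrow(curve)
  nb <- max(5L, floor(baseline_fraction * n))
  base <- curve$force_nn[seq_len(nb)]
  b0 <- mean(base)
  noise <- max(sd(base), 1e-9)
  f <- curve$force_nn - b0
  above <- f > 3 * noise
  # sustained: above threshold and stays above for the next few samples
  run <- which(above & c(above[-(1:3)], TRUE, TRUE, TRUE) &
                 c(above[-(1:2)], TRUE, TRUE))
  run <- run[run > nb / 2]
  if (!length(run)) {
    abort("No contact detected: force never rises above the baseline.",
          class = "slb_no_contact_error")
  }
  i0 <- run[1]
  z <- curve$z_um
  # refine: cp in [z at last clearly-baseline point, z at threshold crossing]
  lo <- z[max(1L, i0 - 50L)]
  hi <- z[i0]
  fit_rss <- function(cp) {
    sel <- z > cp & z <= cp + (hi - lo + 0.5)
    if (sum(sel) < 5) return(Inf)
    xx <- (z[sel] - cp)^exponent
    a <- sum(xx * f[sel]) / sum(xx^2)
    sum((f[sel] - a * xx)^2)
  }
  opt <- optimize(fit_rss, c(lo, hi))
  cp <- opt$minimum
  attr(cp, "baseline") <- b0
  attr(cp, "noise_sd") <- noise
  cp
}

#' Fit the spherical Hertz model to an approach curve
#'
#' Least squares of \eqn{F = \frac{4}{3} \frac{E}{1-\nu^2} \sqrt{R}
#' \delta^{3/2}} over indentations \eqn{\delta = z - z_c} up to
#' `max_indentation`. E is obtained in closed form (the model is linear in E
#' given the contact point); with `fit_contact_point = TRUE` (default) the
#' contact point is jointly optimized over a bracket around the initial
#' estimate, which also makes the fit invariant to a constant force offset
#' (the baseline is re-estimated relative to the contact point).
#'
#' @param curve Force-curve tibble.
#' @param radius_um Indenter sphere radius, um (required; e.g. 18.5 for a
#'   nominal 37 um polystyrene bead).
#' @param poisson_ratio Poisson ratio (default 0.5, incompressible).
#' @param max_indentation_um Fit range past contact (default: all sampled
#'   indentation).
#' @param contact_point Optional fixed contact point, um; default from
#'   [find_contact_point()].
#' @param fit_contact_point Jointly refine the contact point (default `TRUE`).
#' @return A `hertz_fit`: `young_modulus` (Pa), `contact_point` (um),
#'   `poisson_ratio`, `radius_um`, `n_points`, `residual` (nN^2), `flags`.
#' @export
fit_hertz <- function(curve, radius_um, poisson_ratio = 0.5,
                      max_indentation_um = NULL, contact_point = NULL,
                      fit_contact_point = TRUE) {
  check_force_curve(curve)
  check_number(radius_um, "radius_um", lower = 0, allow_equal_lower = FALSE)
  check_number(poisson_ratio, "poisson_ratio", lower = 0, upper = 0.5)
  cp0 <- if (is.null(contact_point)) {
    as.numeric(find_contact_point(curve, exponent = 1.5))
  } else contact_point
  z <- curve$z_um
  fn <- curve$force_nn
  pre <- z < cp0
  b0 <- if (sum(pre) >= 3) mean(fn[pre]) else 0
  max_ind <- max_indentation_um %||% (max(z) - cp0)

  prefac <- function(cp) {
    sel <- z > cp & (z - cp) <= max_ind
    if (sum(sel) < 3) return(NULL)
    delta_m <- (z[sel] - cp) * 1e-6
    xx <- (4 / 3) / (1 - poisson_ratio^2) * sqrt(radius_um * 1e-6) *
      delta_m^1.5 * 1e9            # nN per Pa of E
    list(xx = xx, yy = fn[sel] - b0)
  }
  rss_at <- function(cp) {
    pf <- prefac(cp)
    if (is.null(pf)) return(Inf)
    e_hat <- sum(pf$xx * pf$yy) / sum(pf$xx^2)
    sum((pf$yy - e_hat * pf$xx)^2)
  }
  cp <- cp0
  if (fit_contact_point) {
    span <- max(0.05 * max_ind, 5 * median(diff(z)))
    cp <- optimize(rss_at, c(cp0 - span, cp0 + span))$minimum
    pre <- z < cp
    b0 <- if (sum(pre) >= 3) mean(fn[pre]) else b0
  }
  pf <- prefac(cp)
  if (is.null(pf)) {
    abort("Too few points past the contact point to fit.",
          class = "slb_fit_error")
  }
  e_hat <- sum(pf$xx * pf$yy) / sum(pf$xx^2)
  if (!is.finite(e_hat) || e_hat <= 0) {
    abort("Hertz fit produced a non-positive modulus.",
          class = "slb_fit_error")
  }
  structure(
    list(young_modulus = e_hat, contact_point = cp,
         poisson_ratio = poisson_ratio, radius_um = radius_um,
         n_points = length(pf$xx),
         residual = sum((pf$yy - e_hat * pf$xx)^2),
         baseline = b0,
         flags = character()),
    class = "hertz_fit"
  )
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(
    "Hertz fit: E = %.4g kPa (R = %g um, nu = %g, contact at %.4g um, %d pts)\n",
    x$young_modulus / 1e3, x$radius_um, x$poisson_ratio, x$contact_point,
    x$n_points))
  invisible(x)
}

#' Detect bilayer push-through events in an approach curve
#'
#' Push-through (breakthrough) events appear as a change in the gradient of
#' the force curve: while the tip crosses the bilayer, the piezo advances but
#' the force stays near-constant or falls, between two regions of positive
#' stiffness. The detector computes the local gradient dF/dz by linear
#' regression over a sliding window, flags contiguous in-contact runs where
#' the gradient drops below `drop_threshold` local gradient-noise sds compared
#' to the surrounding stiffness (or reverses sign), and requires positive
#' stiffness on both sides. The z-jump is measured as the horizontal offset
#' between the force branches before and after the event, evaluated at the
#' breakthrough force, which is robust to gradient-window smoothing.
#'
#' @param curve Force-curve tibble; resampled to uniform z spacing before
#'   gradient computation.
#' @param gradient_window Points per sliding regression window (default 7).
#' @param drop_threshold Gradient-drop threshold in multiples of the local
#'   gradient noise sd (default 5).
#' @param sampling_step_nm Uniform resampling step, nm (default: median input
#'   spacing).
#' @param min_force_nn Events are only sought after the force exceeds this
#'   level (default `6 *` baseline force noise), suppressing spurious calls
#'   around the contact point.
#' @return Tibble of events: `z_start_um`, `z_end_um`, `z_jump_nm`,
#'   `breakthrough_force_nn`, `slope_before`, `slope_after` (nN/um),
#'   `slope_ratio`. Zero rows when the curve is smooth.
#' @export
detect_push_through <- function(curve, gradient_window = 7,
                                drop_threshold = 5, sampling_step_nm = NULL,
                                min_force_nn = NULL) {
  check_force_curve(curve)
  z <- curve$z_um; fn <- curve$force_nn
  step_um <- (sampling_step_nm %||% (median(diff(z)) * 1e3)) * 1e-3
  zu <- seq(min(z), max(z), by = step_um)
  fu <- approx(z, fn, xout = zu)$y
  n <- length(zu)
  w <- as.integer(gradient_window)
  if (n < 4 * w) {
    abort("Curve too short for the requested gradient window.",
          class = "slb_input_error")
  }
  # local gradient by centered sliding linear regression
  grad <- sliding_slope(zu, fu, w)

  # baseline statistics from the pre-contact region
  cp_obj <- tryCatch(find_contact_point(curve), error = function(e) NULL)
  cp <- if (is.null(cp_obj)) NA_real_ else as.numeric(cp_obj)
  base_noise <- if (is.null(cp_obj)) {
    max(sd(fu[seq_len(max(5, n %/% 5))]), 1e-9)
  } else {
    max(attr(cp_obj, "noise_sd"), 1e-9)
  }
  min_force <- min_force_nn %||% (6 * base_noise)
  # gradient noise: spread of the gradient over the flat baseline
  pre_idx <- if (is.na(cp)) seq_len(max(5, n %/% 5)) else which(zu < cp)
  if (length(pre_idx) < w) pre_idx <- seq_len(max(w, n %/% 10))
  grad_noise <- max(mad(grad[pre_idx], na.rm = TRUE), 1e-9)

  in_contact <- fu > min_force
  # candidate event points: in contact, gradient not significantly positive
  candidate <- in_contact & (grad < drop_threshold * grad_noise)
  candidate[is.na(candidate)] <- FALSE
  runs <- rle(candidate)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev <- which(runs$values & runs$lengths >= 2L)

  out <- list()
  half <- w %/% 2
  wide <- 3L * w      # longer branch fits for sub-step z-jump refinement
  branch_fit <- function(idx) {
    idx <- idx[idx >= 1L & idx <= n]
    if (length(unique(idx)) < w) return(NULL)
    fit <- lm(fu[idx] ~ zu[idx])
    c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
  }
  for (r in ev) {
    i0 <- starts[r]; i1 <- ends[r]
    # bracketing positive-stiffness windows (shifted past gradient smearing)
    bb <- branch_fit((i0 - half - w):(i0 - half - 1L))
    ba <- branch_fit((i1 + half + 1L):(i1 + half + w))
    if (is.null(bb) || is.null(ba)) next
    slope_b <- bb["slope"]; slope_a <- ba["slope"]
    if (!is.finite(slope_b) || !is.finite(slope_a)) next
    if (slope_b <= drop_threshold * grad_noise ||
        slope_a <= drop_threshold * grad_noise) next
    f_b <- median(fu[i0:i1])          # breakthrough force level
    # z-jump = horizontal offset between the two force branches at the
    # breakthrough force, from longer branch fits (robust to window smearing)
    wb <- branch_fit((i0 - half - wide):(i0 - half - 1L)) %||% bb
    wa <- branch_fit((i1 + half + 1L):(i1 + half + wide)) %||% ba
    z_start <- (f_b - wb["intercept"]) / wb["slope"]
    z_end <- (f_b - wa["intercept"]) / wa["slope"]
    z_jump <- unname(z_end - z_start)
    if (!is.finite(z_jump) || z_jump < 2 * step_um) next
    out[[length(out) + 1L]] <- tibble(
      z_start_um = unname(z_start), z_end_um = unname(z_end),
      z_jump_nm = z_jump * 1e3,
      breakthrough_force_nn = f_b, slope_before = unname(slope_b),
      slope_after = unname(slope_a),
      slope_ratio = unname(slope_b / slope_a)
    )
  }
  if (!length(out)) {
    return(tibble(z_start_um = numeric(), z_end_um = numeric(),
                  z_jump_nm = numeric(), breakthrough_force_nn = numeric(),
                  slope_before = numeric(), slope_after = numeric(),
                  slope_ratio = numeric()))
  }
  arrange(list_rbind(out), .data$z_start_um)
}

# slope of y vs x over a centered window of w points at each index
sliding_slope <- function(x, y, w) {
  n <- length(x)
  half <- w %/% 2
  # uniform x: slope = sum((x - xbar) (y - ybar)) / sum((x - xbar)^2)
  slopes <- rep(NA_real_, n)
  offs <- (-half):half
  denom_x <- x[1 + half + offs] - mean(x[1 + half + offs])
  denom <- sum(denom_x^2)
  for (i in (half + 1):(n - half)) {
    yy <- y[i + offs]
    slopes[i] <- sum(denom_x * (yy - mean(yy))) / denom
  }
  slopes
}

#' Ratio of the slopes before and after a push-through event
#'
#' For a single bilayer on a matched substrate this ratio is close to 1.
#'
#' @param event One row of the [detect_push_through()] output (or any list
#'   with `slope_before` and `slope_after`).
#' @return `slope_before / slope_after`.
#' @export
slope_ratio <- function(event) {
  if (is.null(event$slope_after) || !is.finite(event$slope_after) ||
      event$slope_after == 0) {
    abort("`slope_after` is zero or missing; ratio undefined.",
          class = "slb_degenerate_error")
  }
  event$slope_before / event$slope_after
}
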