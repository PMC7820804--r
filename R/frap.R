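# FRAP analysis: normalization, beam-radius estimation, Axelrod model fit.

#' Normalize a raw FRAP trace
#'
#' Background-subtracts the region-of-interest trace, divides by the
#' (background-subtracted) reference-region trace to correct for acquisition
#' photobleaching, locates the bleach frame as the largest single-frame drop,
#' and rescales so that the mean pre-bleach intensity is 1. Output times are
#' relative to the first post-bleach frame.
#'
#' @param trace Tibble with columns `time`, `roi`, `background` and optionally
#'   `reference` (raw region means).
#' @param prebleach_frames Number of frames recorded before the bleach
#'   (default 10); at least this many frames must precede the detected bleach.
#' @param min_drop Minimum relative single-frame drop that counts as a bleach
#'   event (fraction of the pre-drop level, default 0.1).
#' @return A `frap_trace`: tibble `time`, `intensity` (post-bleach frames
#'   only, time 0 at the first one) with attributes `prebleach_intensity`
#'   (1 after scaling), `postbleach_intensity` (first post-bleach value) and
#'   `bleach_index` in the input trace.
#' @export
normalize_frap <- function(trace, prebleach_frames = 10, min_drop = 0.1) {
  need <- c("time", "roi", "background")
  if (!all(need %in% names(trace))) {
    abort("`trace` needs columns time, roi, background.",
          class = "slb_input_error")
  }
  sig <- trace$roi - trace$background
  if ("reference" %in% names(trace)) {
    ref <- trace$reference - trace$background
    if (any(ref <= 0)) {
      abort("Reference trace must stay above background.",
            class = "slb_input_error")
    }
    sig <- sig / ref
  }
  drops <- -diff(sig)
  rel <- drops / pmax(abs(sig[-length(sig)]), 1e-12)
  bleach_at <- which.max(drops)
  if (length(drops) == 0 || drops[bleach_at] <= 0 ||
      rel[bleach_at] < min_drop) {
    abort("No bleach event detected in the trace.",
          class = "slb_no_bleach_error")
  }
  bleach_index <- bleach_at + 1L   # first post-bleach frame
  if (bleach_index - 1L < prebleach_frames) {
    abort(sprintf("Only %d pre-bleach frames found (%d required).",
                  bleach_index - 1L, prebleach_frames),
          class = "slb_input_error")
  }
  pre <- mean(sig[(bleach_index - prebleach_frames):(bleach_index - 1L)])
  norm <- sig / pre
  post <- seq(bleach_index, length(norm))
  out <- tibble(time = trace$time[post] - trace$time[bleach_index],
                intensity = norm[post])
  attr(out, "prebleach_intensity") <- 1
  attr(out, "postbleach_intensity") <- norm[bleach_index]
  attr(out, "bleach_index") <- bleach_index
  class(out) <- c("frap_trace", class(out))
  out
}

#' Estimate the effective bleach beam radius
#'
#' Fits the post/pre bleach ratio image to the exponential of a 2D Gaussian,
#' \deqn{I_{post}/I_{pre} = \exp(-K e^{-2 r^2 / w^2}),}
#' the profile left by a Gaussian beam of 1/e^2 radius `w` bleaching with
#' depth `K`.
#'
#' @param prebleach_frame,postbleach_frame Registered matrices `[y, x]`.
#' @param pixel_size um per pixel.
#' @return List with `w` (um), `bleach_depth` (K), `center` (pixel coords) and
#'   the fit object.
#' @export
estimate_beam_radius <- function(prebleach_frame, postbleach_frame,
                                 pixel_size = 1) {
  check_matrix(prebleach_frame, "prebleach_frame")
  check_matrix(postbleach_frame, "postbleach_frame")
  if (!all(dim(prebleach_frame) == dim(postbleach_frame))) {
    abort("Frames must have the same dimensions.", class = "slb_input_error")
  }
  ratio <- postbleach_frame / pmax(prebleach_frame, 1e-12)
  ny <- nrow(ratio); nx <- ncol(ratio)
  df <- data.frame(
    v = as.vector(ratio),
    x = rep(seq_len(nx) - 1, each = ny) * pixel_size,
    y = rep(seq_len(ny) - 1, times = nx) * pixel_size
  )
  imin <- which.min(ratio)
  x0 <- ((imin - 1) %/% ny) * pixel_size
  y0 <- ((imin - 1) %% ny) * pixel_size
  k0 <- max(-log(max(min(ratio), 1e-6)), 1e-3)
  # initial w: area where bleaching exceeds half depth ~ pi w^2 ln2 / 2
  n_deep <- sum(ratio < exp(-k0 / 2))
  w0 <- max(sqrt(2 * n_deep / (pi * log(2))) * pixel_size,
            pixel_size)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ exp(-K * exp(-2 * ((x - cx)^2 + (y - cy)^2) / w^2)),
      data = df,
      start = list(K = k0, cx = x0, cy = y0, w = w0),
      lower = c(K = 1e-4, cx = -Inf, cy = -Inf, w = pixel_size / 10),
      control = nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    abort("Beam-profile fit did not converge.", class = "slb_fit_error")
  }
  p <- coef(fit)
  if (p["K"] < 0.05) {
    abort("No appreciable bleaching detected (K < 0.05); cannot estimate w.",
          class = "slb_fit_error")
  }
  list(w = unname(p["w"]), bleach_depth = unname(p["K"]),
       center = c(x = unname(p["cx"]), y = unname(p["cy"])), fit = fit)
}

#' Mobile fraction from recovery intensities
#'
#' \deqn{f_{mobile} = \frac{F_\infty - F_0}{F_i - F_0}}
#' with \eqn{F_i} the pre-bleach, \eqn{F_0} the immediate post-bleach and
#' \eqn{F_\infty} the asymptotic intensity. Values outside `[0, 1]` are
#' clamped and flagged via the `"clamped"` attribute.
#'
#' @param f_i Pre-bleach intensity.
#' @param f0 Intensity immediately after bleaching.
#' @param f_inf Asymptotic recovered intensity.
#' @return The mobile fraction in `[0, 1]`.
#' @examples
#' mobile_fraction(1.0, 0.4, 0.85)  # 0.75
#' @export
mobile_fraction <- function(f_i, f0, f_inf) {
  if (f_i <= f0) {
    abort("`f_i` must exceed `f0` (no bleach depth).",
          class = "slb_parameter_error")
  }
  f <- (f_inf - f0) / (f_i - f0)
  clamped <- f < 0 || f > 1
  if (clamped) {
    warn(sprintf("Mobile fraction %.3f outside [0, 1]; clamped.", f))
    f <- min(max(f, 0), 1)
  }
  attr(f, "clamped") <- clamped
  f
}

#' Fit the Axelrod recovery model to a normalized FRAP trace
#'
#' Nonlinear least squares of [axelrod_recovery()] for the bleach depth K,
#' characteristic diffusion time tau_D and mobile fraction M_f; the immobile
#' baseline uses the first post-bleach intensity F_0 of the trace. The
#' diffusion coefficient follows as \eqn{D = w^2 / (4 \tau_D)}. A half-time
#' estimate \eqn{D_{1/2} = 0.88\, w^2 / (4 t_{1/2})} is also reported for
#' comparison.
#'
#' Initialization: K from the observed bleach depth, tau from the
#' half-recovery time, M_f from the mean of the last decile; bounds
#' K in (0, 10], tau in (0, 10 t_max], M_f in \[0, 1\].
#'
#' @param trace A `frap_trace` (see [normalize_frap()] or
#'   [simulate_frap_curve()]).
#' @param beam_radius Effective beam radius w, um.
#' @return A `frap_fit` object: `bleach_depth`, `tau_d` (s),
#'   `mobile_fraction`, `d_coef` (um^2/s), `d_halftime` (um^2/s), `f0`,
#'   `f_inf`, `beam_radius`, `residual`, `flags`.
#' @export
fit_axelrod <- function(trace, beam_radius) {
  check_number(beam_radius, "beam_radius", lower = 0,
               allow_equal_lower = FALSE)
  t <- trace$time; yv <- trace$intensity
  if (length(t) < 5) {
    abort("Trace too short to fit.", class = "slb_input_error")
  }
  f0 <- attr(trace, "postbleach_intensity", exact = TRUE) %||% yv[1]
  t_max <- max(t)
  # initial values
  f_end <- mean(yv[t >= quantile(t, 0.9)])
  mf0 <- min(max((f_end - f0) / (1 - f0), 0.05), 1)
  k0 <- min(max(-log(max(f0, 1e-3)) * 1.5, 0.05), 10)
  half_level <- f0 + 0.5 * (f_end - f0)
  above <- which(yv >= half_level)
  tau0 <- if (length(above)) max(t[above[1]], t_max / 100) else t_max / 5
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yv ~ axelrod_recovery(t, K, tau, mf, f0),
      start = list(K = k0, tau = tau0, mf = mf0),
      lower = c(K = 1e-4, tau = 1e-6, mf = 0),
      upper = c(K = 10, tau = 10 * t_max, mf = 1),
      control = nls.control(maxiter = 500, warnOnly = TRUE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    abort(paste("Axelrod fit failed:", conditionMessage(fit)),
          class = "slb_fit_error")
  }
  p <- coef(fit)
  flags <- character()
  if (p["tau"] >= 10 * t_max * 0.999 || p["K"] >= 10 * 0.999) {
    flags <- c(flags, "parameter_at_bound")
  }
  f_inf <- unname(p["mf"]) + (1 - unname(p["mf"])) * f0
  half_target <- f0 + 0.5 * (f_inf - f0)
  fitted_curve <- axelrod_recovery(t, unname(p["K"]), unname(p["tau"]),
                                   unname(p["mf"]), f0)
  idx <- which(fitted_curve >= half_target)
  t_half <- if (length(idx)) t[idx[1]] else NA_real_
  structure(
    list(bleach_depth = unname(p["K"]), tau_d = unname(p["tau"]),
         mobile_fraction = unname(p["mf"]),
         d_coef = beam_radius^2 / (4 * unname(p["tau"])),
         d_halftime = if (is.na(t_half) || t_half <= 0) NA_real_ else
           0.88 * beam_radius^2 / (4 * t_half),
         f0 = f0, f_inf = f_inf, beam_radius = beam_radius,
         residual = sum((yv - fitted_curve)^2), n_points = length(t),
         flags = flags),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "Axelrod FRAP fit: D = %.4g um^2/s (tau_D = %.3g s, w = %.3g um)\n",
    x$d_coef, x$tau_d, x$beam_radius))
  cat(sprintf("  mobile fraction = %.3f, bleach depth K = %.3g\n",
              x$mobile_fraction, x$bleach_depth))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
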