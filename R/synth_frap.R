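#' Axelrod recovery model for Gaussian-beam FRAP
#'
#' Closed-form fractional recovery after photobleaching a 2D membrane with a
#' Gaussian laser beam:
#' \deqn{F(t) = M_f \sum_{n \ge 0} \frac{(-K)^n}{n!}\,
#'   \frac{1}{1 + n(1 + 2t/\tau_D)} + (1 - M_f) F_0}
#' where \eqn{K} is the bleach depth, \eqn{\tau_D} the characteristic
#' diffusion time, \eqn{M_f} the mobile fraction and \eqn{F_0} the normalized
#' intensity immediately after the bleach (the immobile part never recovers
#' above \eqn{F_0}). The series is truncated when a term falls below `1e-10`
#' in absolute value or at `n = 60`, whichever comes first. Useful limits:
#' \eqn{F(0) = (1 - e^{-K})/K} (for \eqn{M_f = 1}) and
#' \eqn{F(\infty) = M_f + (1 - M_f) F_0}.
#'
#' @param t Time since the bleach, s (vector).
#' @param bleach_depth Bleach-depth parameter K (> 0).
#' @param tau_d Characteristic diffusion time, s (> 0).
#' @param mobile_fraction Mobile fraction in `[0, 1]`.
#' @param f0 Normalized intensity of the first post-bleach frame.
#' @return Numeric vector of normalized intensities.
#' @export
axelrod_recovery <- function(t, bleach_depth, tau_d, mobile_fraction = 1,
                             f0 = 0) {
  check_number(bleach_depth, "bleach_depth", lower = 0,
               allow_equal_lower = FALSE)
  check_number(tau_d, "tau_d", lower = 0, allow_equal_lower = FALSE)
  check_number(mobile_fraction, "mobile_fraction", lower = 0, upper = 1)
  s <- rep(0, length(t))
  term <- rep(1, length(t))      # n = 0 term: 1 / (1 + 0)
  s <- s + term
  coef_n <- 1
  for (n in 1:60) {
    coef_n <- coef_n * (-bleach_depth) / n
    term <- coef_n / (1 + n * (1 + 2 * t / tau_d))
    s <- s + term
    if (max(abs(term)) < 1e-10) break
  }
  mobile_fraction * s + (1 - mobile_fraction) * f0
}

#' Simulate a FRAP recovery trace
#'
#' Evaluates the Axelrod model ([axelrod_recovery()]) on the requested
#' post-bleach time grid and adds Gaussian measurement noise, producing a
#' normalized trace as output by [normalize_frap()].
#'
#' @param timepoints Times since the bleach, s; must start at 0 (the first
#'   post-bleach frame).
#' @param bleach_depth,tau_d,mobile_fraction Model parameters (see
#'   [axelrod_recovery()]).
#' @param f0 Normalized first post-bleach intensity used for the immobile
#'   baseline term.
#' @param noise_sd Gaussian noise sd in normalized-intensity units.
#' @param seed Integer seed.
#' @return A `frap_trace`: tibble with `time`, `intensity`, carrying
#'   `prebleach_intensity` (1 by construction) and `postbleach_intensity`
#'   attributes plus the `ground_truth` parameters.
#' @examples
#' tr <- simulate_frap_curve(0:180, bleach_depth = 1, tau_d = 2,
#'                           mobile_fraction = 0.9, f0 = 0.3, noise_sd = 0.01,
#'                           seed = 1)
#' @export
simulate_frap_curve <- function(timepoints, bleach_depth, tau_d,
                                mobile_fraction, f0, noise_sd = 0,
                                seed = NULL) {
  if (length(timepoints) < 3 || timepoints[1] != 0 ||
      any(diff(timepoints) <= 0)) {
    abort("`timepoints` must start at 0 and be strictly increasing.",
          class = "slb_parameter_error")
  }
  clean <- axelrod_recovery(timepoints, bleach_depth, tau_d, mobile_fraction,
                            f0)
  intensity <- if (noise_sd > 0) {
    with_seed(seed, clean + rnorm(length(clean), sd = noise_sd))
  } else clean
  out <- tibble(time = as.numeric(timepoints), intensity = intensity)
  attr(out, "prebleach_intensity") <- 1
  attr(out, "postbleach_intensity") <- f0
  attr(out, "ground_truth") <- list(
    bleach_depth = bleach_depth, tau_d = tau_d,
    mobile_fraction = mobile_fraction, f0 = f0, noise_sd = noise_sd,
    seed = seed
  )
  class(out) <- c("frap_trace", class(out))
  out
}
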