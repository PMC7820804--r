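#' Simulate a population of single-cell calcium traces
#'
#' Emulates Fluo-4/GCaMP intensity traces from a T cell activation experiment:
#' a fraction of cells respond with one or more calcium transients, a fraction
#' of those responders fire repeatedly ("blinking"), and the remainder stay at
#' baseline. Transients are Gaussian-shaped pulses whose amplitude is expressed
#' in multiples of the baseline; first-peak latencies are exponentially
#' distributed (truncated to the first 80% of the movie) and extra peaks of
#' multi-peak responders are placed uniformly after the first.
#'
#' @param n_cells Number of cells.
#' @param responder_fraction Probability a cell responds (>= 1 peak).
#' @param multipeak_fraction Probability a responder fires > 1 peak.
#' @param baseline_level Resting intensity, a.u.
#' @param peak_height_range Peak amplitude in baseline multiples, sampled
#'   uniformly in this range (values > 1; height multiple = peak/baseline).
#' @param peak_width Gaussian sd of a transient, s.
#' @param latency_mean Mean of the exponential part of the first-peak
#'   latency, s.
#' @param latency_offset Minimum first-peak latency, s (default 20): cells
#'   must land on and engage the surface before signaling, so no transient
#'   starts inside the baseline-estimation window.
#' @param noise_sd Gaussian noise sd, a.u.
#' @param duration Movie length, s.
#' @param frame_interval Time between frames, s.
#' @param seed Integer seed.
#' @return Tibble with `cell_id`, `time`, `intensity`; `ground_truth`
#'   attribute holds a per-cell tibble (`cell_id`, `responder`, `multipeak`,
#'   `n_peaks`, `first_peak_time`) plus the generator parameters.
#' @examples
#' pop <- simulate_calcium_population(20, responder_fraction = 0.5, seed = 1)
#' dplyr::count(ground_truth(pop)$cells, responder)
#' @export
simulate_calcium_population <- function(n_cells,
                                        responder_fraction = 0.7,
                                        multipeak_fraction = 0.3,
                                        baseline_level = 100,
                                        peak_height_range = c(3, 8),
                                        peak_width = 10,
                                        latency_mean = 90,
                                        latency_offset = 20,
                                        noise_sd = 2,
                                        duration = 600,
                                        frame_interval = 1,
                                        seed = NULL) {
  check_number(n_cells, "n_cells", lower = 1)
  check_number(responder_fraction, "responder_fraction", lower = 0, upper = 1)
  check_number(multipeak_fraction, "multipeak_fraction", lower = 0, upper = 1)
  check_number(baseline_level, "baseline_level", lower = 0,
               allow_equal_lower = FALSE)
  if (any(peak_height_range <= 1)) {
    abort("`peak_height_range` must be > 1 (multiples of baseline).",
          class = "slb_parameter_error")
  }
  if (duration / frame_interval < 10) {
    abort("Need at least 10 frames (duration / frame_interval >= 10).",
          class = "slb_parameter_error")
  }
  times <- seq(0, duration, by = frame_interval)
  with_seed(seed, {
    responder <- runif(n_cells) < responder_fraction
    multipeak <- responder & (runif(n_cells) < multipeak_fraction)
    n_peaks <- integer(n_cells)
    n_peaks[responder] <- 1L
    n_peaks[multipeak] <- 2L + rpois(sum(multipeak), 0.7)
    traces <- vector("list", n_cells)
    first_peak <- rep(NA_real_, n_cells)
    for (i in seq_len(n_cells)) {
      y <- rep(baseline_level, length(times))
      if (n_peaks[i] > 0) {
        t1 <- min(latency_offset + rexp(1, 1 / latency_mean), 0.8 * duration)
        extra <- if (n_peaks[i] > 1) {
          lo <- min(t1 + 4 * peak_width, 0.9 * duration)
          runif(n_peaks[i] - 1L, min = lo, max = 0.98 * duration)
        } else numeric()
        centers <- c(t1, extra)
        first_peak[i] <- t1
        heights <- runif(n_peaks[i], peak_height_range[1],
                         peak_height_range[2])
        for (j in seq_along(centers)) {
          y <- y + baseline_level * (heights[j] - 1) *
            exp(-(times - centers[j])^2 / (2 * peak_width^2))
        }
      }
      if (noise_sd > 0) y <- y + rnorm(length(y), sd = noise_sd)
      traces[[i]] <- tibble(cell_id = i, time = times, intensity = y)
    }
    out <- list_rbind(traces)
    attr(out, "ground_truth") <- list(
      cells = tibble(cell_id = seq_len(n_cells), responder = responder,
                     multipeak = multipeak, n_peaks = n_peaks,
                     first_peak_time = first_peak),
      params = list(responder_fraction = responder_fraction,
                    multipeak_fraction = multipeak_fraction,
                    baseline_level = baseline_level,
                    peak_height_range = peak_height_range,
                    peak_width = peak_width, latency_mean = latency_mean,
                    latency_offset = latency_offset,
                    noise_sd = noise_sd, duration = duration,
                    frame_interval = frame_interval, seed = seed)
    )
    out
  })
}
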