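#' Simulate 2D Brownian single-particle tracks
#'
#' Generates trajectories for a mixture of freely diffusing populations, as
#' imaged in single-molecule TIRF experiments on supported lipid bilayers.
#' Each track is assigned to one diffusive component with probability given by
#' `fractions`; per-frame displacements along each axis are Gaussian with
#' variance `2 * D * frame_interval`, and independent Gaussian localization
#' noise of standard deviation `sigma_loc` is added to every coordinate
#' (static localization error). Motion blur is not simulated at the trajectory
#' level; it enters only through the exposure-time term of the MSD fit model
#' (see [fit_msd()]).
#'
#' @param n_tracks Number of tracks.
#' @param track_length Number of frames per track (>= 2).
#' @param d_coef Diffusion coefficient(s), um^2/s, one per component.
#' @param fractions Mixture fractions, same length as `d_coef`, summing to 1.
#' @param sigma_loc Localization precision (standard deviation per coordinate),
#'   um.
#' @param frame_interval Time between frames, s.
#' @param exposure_time Camera exposure, s (recorded as metadata; the
#'   trajectories themselves are instantaneous positions).
#' @param seed Integer seed for reproducibility; `NULL` uses the current RNG
#'   state.
#' @return A tibble with columns `particle_id`, `component`, `frame`, `x`, `y`
#'   (positions in um). The generating parameters are attached as the
#'   `ground_truth` attribute (see [ground_truth()]).
#' @examples
#' trk <- simulate_tracks(50, 20, d_coef = 1.0, frame_interval = 0.01, seed = 1)
#' compute_ensemble_msd(trk, frame_interval = 0.01)
#' @export
simulate_tracks <- function(n_tracks, track_length, d_coef,
                            fractions = rep(1 / length(d_coef), length(d_coef)),
                            sigma_loc = 0, frame_interval = 0.01,
                            exposure_time = frame_interval, seed = NULL) {
  check_number(n_tracks, "n_tracks", lower = 1)
  check_number(track_length, "track_length", lower = 2)
  if (length(d_coef) != length(fractions)) {
    abort("`d_coef` and `fractions` must have the same length.",
          class = "slb_parameter_error")
  }
  if (any(d_coef < 0)) {
    abort("Diffusion coefficients must be >= 0.", class = "slb_parameter_error")
  }
  check_fractions(fractions)
  check_number(sigma_loc, "sigma_loc", lower = 0)
  check_number(frame_interval, "frame_interval", lower = 0,
               allow_equal_lower = FALSE)

  n_tracks <- as.integer(n_tracks)
  track_length <- as.integer(track_length)
  with_seed(seed, {
    comp <- sample.int(length(d_coef), n_tracks, replace = TRUE,
                       prob = fractions)
    step_sd <- sqrt(2 * d_coef[comp] * frame_interval)
    n_steps <- track_length - 1L
    # displacement matrices: rows = steps, cols = tracks
    dx <- matrix(rnorm(n_steps * n_tracks), n_steps, n_tracks) *
      rep(step_sd, each = n_steps)
    dy <- matrix(rnorm(n_steps * n_tracks), n_steps, n_tracks) *
      rep(step_sd, each = n_steps)
    x <- rbind(0, apply(dx, 2, cumsum))
    y <- rbind(0, apply(dy, 2, cumsum))
    if (sigma_loc > 0) {
      x <- x + rnorm(length(x), sd = sigma_loc)
      y <- y + rnorm(length(y), sd = sigma_loc)
    }
    out <- tibble(
      particle_id = rep(seq_len(n_tracks), each = track_length),
      component = rep(comp, each = track_length),
      frame = rep(seq_len(track_length), times = n_tracks),
      x = as.vector(x),
      y = as.vector(y)
    )
    attr(out, "ground_truth") <- list(
      d_coef = d_coef, fractions = fractions, sigma_loc = sigma_loc,
      frame_interval = frame_interval, exposure_time = exposure_time,
      n_tracks = n_tracks, track_length = track_length, seed = seed
    )
    out
  })
}
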