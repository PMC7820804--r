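#' Filter tracks by minimum length
#'
#' Diffusion analysis uses only tracks longer than five frames (i.e. at least
#' six localizations) by default.
#'
#' @param tracks Tibble with `particle_id` and `frame` columns.
#' @param min_length Minimum number of frames a track must have to be kept
#'   (default 6, i.e. tracks longer than 5 frames).
#' @return The filtered tibble; a warning is issued if nothing survives.
#' @export
filter_tracks <- function(tracks, min_length = 6) {
  if (nrow(tracks) == 0) return(tracks)
  len <- table(tracks$particle_id)
  keep_ids <- names(len)[len >= min_length]
  out <- tracks[as.character(tracks$particle_id) %in% keep_ids, ]
  if (nrow(out) == 0) warn("All tracks removed by the length filter.")
  for (a in c("frame_interval", "pixel_size", "ground_truth")) {
    attr(out, a) <- attr(tracks, a, exact = TRUE)
  }
  out
}

#' Ensemble mean-square displacement
#'
#' Pools squared displacements over all tracks and all start frames
#' (overlapping windows) for each lag, the standard ensemble estimator for
#' lipid and receptor diffusion in bilayers. The standard error at each lag is
#' computed from the pooled sample of squared displacements.
#'
#' @param tracks Tibble with `particle_id`, `frame`, `x`, `y` (um).
#' @param frame_interval s between frames; taken from the tracks'
#'   `frame_interval` attribute when present.
#' @param max_lag Largest lag (in frames) to evaluate; default
#'   `min(10, longest track - 1)`.
#' @return An `msd_curve` tibble with `lag` (frames), `lag_time` (s), `msd`
#'   (um^2), `sem` (um^2) and `n_obs` (pooled displacement count), with an
#'   `n_tracks` attribute.
#' @export
compute_ensemble_msd <- function(tracks, frame_interval = NULL,
                                 max_lag = NULL) {
  if (nrow(tracks) == 0) {
    abort("No tracks supplied.", class = "slb_input_error")
  }
  frame_interval <- frame_interval %||%
    attr(tracks, "frame_interval", exact = TRUE)
  if (is.null(frame_interval)) {
    abort("`frame_interval` is required (argument or tracks attribute).",
          class = "slb_parameter_error")
  }
  tl <- split(tracks[c("frame", "x", "y")], tracks$particle_id)
  longest <- max(vapply(tl, nrow, integer(1)))
  if (is.null(max_lag)) max_lag <- min(10L, longest - 1L)
  if (max_lag >= longest) {
    abort("`max_lag` exceeds the longest track.", class = "slb_input_error")
  }
  res <- lapply(seq_len(max_lag), function(lag) {
    sq <- unlist(lapply(tl, function(tr) {
      n <- nrow(tr)
      if (n <= lag) return(numeric())
      i <- seq_len(n - lag)
      # tracks have no gaps (linking contract), so row offset == frame lag
      (tr$x[i + lag] - tr$x[i])^2 + (tr$y[i + lag] - tr$y[i])^2
    }), use.names = FALSE)
    tibble(lag = lag, lag_time = lag * frame_interval,
           msd = mean(sq), sem = sd(sq) / sqrt(length(sq)),
           n_obs = length(sq))
  })
  out <- list_rbind(res)
  attr(out, "n_tracks") <- length(tl)
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("msd_curve", class(out))
  out
}

#' Fit the corrected linear MSD model
#'
#' Least-squares fit of the first `n_points` lags of an ensemble MSD curve to
#' \deqn{\mathrm{MSD}(t) = 4 D t + 4\sigma^2 - \tfrac{4}{3} D t_E}
#' where \eqn{t} is the lag time, \eqn{\sigma} the static localization
#' precision and \eqn{t_E} the camera exposure time (motion-blur correction).
#' `blur_model = "lag"` instead reads the correction term's time as the lag
#' itself, collapsing the model to \eqn{\mathrm{MSD} = \tfrac{8}{3} D t +
#' 4\sigma^2}; the exposure-time reading is the default.
#'
#' A negative fitted slope or offset is clamped to zero and flagged rather
#' than silently reported.
#'
#' @param curve An `msd_curve` from [compute_ensemble_msd()].
#' @param n_points Number of initial lags to fit (default 5).
#' @param exposure_time Camera exposure t_E, s (used by the default model).
#' @param blur_model `"exposure"` (default) or `"lag"`.
#' @return An `msd_fit` object: list with `d_coef` (um^2/s), `sigma_loc` (um),
#'   `offset` (the fitted intercept, um^2), `exposure_time`, `n_points`,
#'   `residual` (RSS over the fitted points), `flags`.
#' @export
fit_msd <- function(curve, n_points = 5, exposure_time = 0,
                    blur_model = c("exposure", "lag")) {
  blur_model <- match.arg(blur_model)
  if (nrow(curve) < n_points) {
    abort("`curve` has fewer lags than `n_points`.", class = "slb_input_error")
  }
  if (n_points < 2) {
    abort("Need at least 2 points to fit.", class = "slb_parameter_error")
  }
  d <- curve[seq_len(n_points), ]
  fit <- lm(msd ~ lag_time, data = d)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  flags <- character()
  if (blur_model == "exposure") {
    d_coef <- slope / 4
    if (d_coef < 0) { d_coef <- 0; flags <- c(flags, "negative_D_clamped") }
    sigma_sq <- (intercept + (4 / 3) * d_coef * exposure_time) / 4
  } else {
    d_coef <- slope * 3 / 8
    if (d_coef < 0) { d_coef <- 0; flags <- c(flags, "negative_D_clamped") }
    sigma_sq <- intercept / 4
  }
  if (sigma_sq < 0) {
    sigma_sq <- 0
    flags <- c(flags, "negative_sigma_sq_clamped")
  }
  structure(
    list(d_coef = d_coef, sigma_loc = sqrt(sigma_sq), offset = intercept,
         exposure_time = exposure_time, blur_model = blur_model,
         n_points = n_points, residual = sum(fit$residuals^2),
         n_tracks = attr(curve, "n_tracks", exact = TRUE), flags = flags),
    class = "msd_fit"
  )
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf(
    "MSD fit (%d points, %s model): D = %.4g um^2/s, sigma_loc = %.4g um\n",
    x$n_points, x$blur_model, x$d_coef, x$sigma_loc))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
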