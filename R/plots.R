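# ggplot2 visualization helpers

#' Plot an ensemble MSD curve with its linear fit
#'
#' @param object An `msd_curve` from [compute_ensemble_msd()].
#' @param fit Optional `msd_fit` from [fit_msd()]; its fitted line is overlaid
#'   over the fitted lags.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_time,
                                           y = .data$msd)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$msd - .data$sem,
                                        ymax = .data$msd + .data$sem),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lag time (s)", y = expression(MSD ~ (mu * m^2)))
  if (!is.null(fit)) {
    d <- object[seq_len(fit$n_points), ]
    slope <- if (fit$blur_model == "exposure") 4 * fit$d_coef else
      (8 / 3) * fit$d_coef
    d$fitted <- fit$offset + slope * d$lag_time
    p <- p + ggplot2::geom_line(data = d,
                                ggplot2::aes(y = .data$fitted),
                                color = "red3")
  }
  p
}

#' Plot a FRAP trace with an Axelrod fit
#'
#' @param object A `frap_trace`.
#' @param fit Optional `frap_fit` from [fit_axelrod()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot frap_trace
#' @export
autoplot.frap_trace <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "time after bleach (s)",
                  y = "normalized intensity")
  if (!is.null(fit)) {
    tt <- seq(min(object$time), max(object$time), length.out = 300)
    d <- tibble(time = tt,
                intensity = axelrod_recovery(tt, fit$bleach_depth, fit$tau_d,
                                             fit$mobile_fraction, fit$f0))
    p <- p + ggplot2::geom_line(data = d, color = "red3")
  }
  p
}

#' Plot a force curve with detected push-through events
#'
#' @param object A force-curve tibble (`z_um`, `force_nn`).
#' @param events Optional events tibble from [detect_push_through()]; event
#'   extents are shaded.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot force_curve
#' @export
autoplot.force_curve <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$z_um, y = .data$force_nn)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = expression(z ~ (mu * m)), y = "force (nN)")
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_rect(
      data = events,
      ggplot2::aes(xmin = .data$z_start_um, xmax = .data$z_end_um,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.2, fill = "red3")
  }
  p
}

#' Plot per-cell calcium traces with detected peaks
#'
#' @param traces Tibble with `cell_id`, `time`, `intensity`.
#' @param peaks Optional output of [detect_peaks()].
#' @param cells Optional subset of cell ids to show.
#' @return A ggplot, faceted by cell.
#' @export
plot_calcium_traces <- function(traces, peaks = NULL, cells = NULL) {
  if (!is.null(cells)) {
    traces <- filter(traces, .data$cell_id %in% cells)
    if (!is.null(peaks)) peaks <- filter(peaks, .data$cell_id %in% cells)
  }
  p <- ggplot2::ggplot(traces, ggplot2::aes(x = .data$time,
                                            y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_id), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "intensity (a.u.)")
  if (!is.null(peaks) && nrow(peaks)) {
    peaks <- mutate(peaks,
                    intensity = .data$height_multiple * .data$baseline)
    p <- p + ggplot2::geom_point(data = peaks, color = "red3", size = 1)
  }
  p
}

#' Show exclusion masks over the probe channel
#'
#' @param result An `exclusion_result` from [compute_exclusion()].
#' @param channel_probe The probe image the result was computed from.
#' @return A ggplot of the probe channel with contact and cell mask outlines.
#' @export
plot_exclusion <- function(result, channel_probe) {
  ny <- nrow(channel_probe); nx <- ncol(channel_probe)
  d <- tibble(
    x = rep(seq_len(nx) - 1, each = ny),
    y = rep(seq_len(ny) - 1, times = nx),
    intensity = as.vector(channel_probe),
    region = dplyr::case_when(
      as.vector(result$contact_mask) ~ "contact",
      as.vector(result$cell_mask) ~ "cell",
      TRUE ~ "background"
    )
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = filter(d, .data$region != "background"),
                        ggplot2::aes(color = .data$region), size = 0.01,
                        alpha = 0.15) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("exclusion = %.2f", result$exclusion))
}
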