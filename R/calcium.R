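# calcium-trace extraction and signaling metrics

#' Extract per-cell calcium traces from a time-lapse stack
#'
#' Per frame: Gaussian smoothing, Otsu threshold ([otsu_threshold()]),
#' connected components of at least `min_cell_area` pixels. Components are
#' tracked across frames by nearest-centroid matching within `max_move`
#' pixels; unmatched components start new cells. The trace value is the mean
#' raw intensity over the component's pixels in that frame.
#'
#' @param stack Numeric array `[y, x, frame]`.
#' @param min_cell_area Minimum component area, pixels.
#' @param frame_interval s between frames.
#' @param smooth_sigma Gaussian smoothing sigma before thresholding, pixels.
#' @param max_move Maximum centroid movement between frames, pixels.
#' @return Tibble with `cell_id`, `frame`, `time`, `intensity`, plus a
#'   `valid_from` column (time the cell was first detected). Empty (with a
#'   warning) if no cells are found.
#' @export
extract_traces <- function(stack, min_cell_area = 20, frame_interval = 1,
                           smooth_sigma = 2, max_move = 10) {
  n_frames <- dim(stack)[3]
  cells_x <- numeric(); cells_y <- numeric()  # last known centroids
  first_frame <- integer()
  rows <- list()
  for (k in seq_len(n_frames)) {
    img <- stack[, , k]
    sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = smooth_sigma))
    thr <- tryCatch(otsu_threshold(sm), error = function(e) NULL)
    if (is.null(thr)) next
    lab <- EBImage::bwlabel(EBImage::Image(sm > thr))
    labm <- as.matrix(lab)
    if (max(labm) == 0) next
    sizes <- tabulate(labm[labm > 0])
    comps <- which(sizes >= min_cell_area)
    if (!length(comps)) next
    for (comp in comps) {
      idx <- which(labm == comp, arr.ind = TRUE)
      cy <- mean(idx[, 1] - 1); cx <- mean(idx[, 2] - 1)
      meanv <- mean(img[labm == comp])
      # match to nearest existing cell
      id <- NA_integer_
      if (length(cells_x)) {
        d2 <- (cells_x - cx)^2 + (cells_y - cy)^2
        j <- which.min(d2)
        if (d2[j] <= max_move^2) id <- j
      }
      if (is.na(id)) {
        cells_x <- c(cells_x, cx); cells_y <- c(cells_y, cy)
        first_frame <- c(first_frame, k)
        id <- length(cells_x)
      } else {
        cells_x[id] <- cx; cells_y[id] <- cy
      }
      rows[[length(rows) + 1L]] <- tibble(cell_id = id, frame = k,
                                          intensity = meanv)
    }
  }
  if (!length(rows)) {
    warn("No cells detected in the stack.")
    return(tibble(cell_id = integer(), frame = integer(), time = numeric(),
                  intensity = numeric(), valid_from = numeric()))
  }
  out <- list_rbind(rows)
  # a cell can only contribute one row per frame; keep the brightest match
  out <- out |>
    group_by(.data$cell_id, .data$frame) |>
    summarise(intensity = max(.data$intensity), .groups = "drop") |>
    mutate(time = (.data$frame - 1) * frame_interval)
  vf <- tibble(cell_id = seq_along(first_frame),
               valid_from = (first_frame - 1) * frame_interval)
  out <- left_join(out, vf, by = "cell_id")
  arrange(out, .data$cell_id, .data$frame)
}

#' Detect calcium transients in per-cell traces
#'
#' Finds local maxima whose height is at least `min_height_multiple` times the
#' cell's baseline and whose topographic prominence is at least
#' `min_prominence_multiple` times the baseline. The baseline is the median of
#' the first `baseline_frames` valid frames of the trace. Each peak's
#' integrated intensity is the baseline-subtracted area (trapezoidal) over the
#' peak's prominence window.
#'
#' @param traces Tibble with `cell_id`, `time`, `intensity` (e.g. from
#'   [extract_traces()] or [simulate_calcium_population()]).
#' @param min_height_multiple Minimum peak height in baseline multiples
#'   (default 1.5).
#' @param min_prominence_multiple Minimum prominence in baseline multiples
#'   (default 0.5).
#' @param baseline_frames Frames used for the baseline median (default 10).
#' @return Tibble with `cell_id`, `time`, `height_multiple`, `prominence`,
#'   `integrated_intensity`, `baseline`.
#' @export
detect_peaks <- function(traces, min_height_multiple = 1.5,
                         min_prominence_multiple = 0.5,
                         baseline_frames = 10) {
  per_cell <- split(traces, traces$cell_id)
  out <- lapply(per_cell, function(tr) {
    tr <- tr[order(tr$time), ]
    y <- tr$intensity; tt <- tr$time
    base <- median(head(y, baseline_frames))
    if (!is.finite(base) || base <= 0) {
      abort("Non-positive baseline; cannot express peaks in multiples.",
            class = "slb_input_error")
    }
    pk <- find_peaks_prominence(y, min_height = min_height_multiple * base)
    if (!nrow(pk)) return(NULL)
    keep <- pk$prominence >= min_prominence_multiple * base
    pk <- pk[keep, , drop = FALSE]
    if (!nrow(pk)) return(NULL)
    integ <- vapply(seq_len(nrow(pk)), function(i) {
      w <- pk$left_base[i]:pk$right_base[i]
      yy <- pmax(y[w] - base, 0)
      sum(diff(tt[w]) * (head(yy, -1) + tail(yy, -1)) / 2)
    }, numeric(1))
    tibble(cell_id = tr$cell_id[1], time = tt[pk$index],
           height_multiple = y[pk$index] / base,
           prominence = pk$prominence,
           integrated_intensity = integ, baseline = base)
  })
  res <- list_rbind(out[!vapply(out, is.null, logical(1))])
  if (nrow(res) == 0) {
    return(tibble(cell_id = integer(), time = numeric(),
                  height_multiple = numeric(), prominence = numeric(),
                  integrated_intensity = numeric(), baseline = numeric()))
  }
  res
}

# local maxima with topographic prominence; returns index, prominence and the
# bases of the prominence window. `min_height` prunes candidates before the
# (relatively costly) prominence walk.
find_peaks_prominence <- function(y, min_height = -Inf) {
  n <- length(y)
  empty <- tibble(index = integer(), prominence = numeric(),
                  left_base = integer(), right_base = integer())
  if (n < 3) return(empty)
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  is_peak <- is_peak[y[is_peak] >= min_height]
  if (!length(is_peak)) return(empty)
  m <- length(is_peak)
  idx <- integer(m); prom <- numeric(m)
  lb <- integer(m); rb <- integer(m)
  for (j in seq_len(m)) {
    i <- is_peak[j]
    # walk left until a higher point; the base is the minimum on that stretch
    lhs <- if (i > 1) {
      higher <- which(y[1:(i - 1)] > y[i])
      lo <- if (length(higher)) max(higher) + 1L else 1L
      lo - 1L + which.min(y[lo:(i - 1)])
    } else i
    rhs <- if (i < n) {
      higher <- which(y[(i + 1):n] > y[i])
      hi <- if (length(higher)) i + min(higher) - 1L else n
      i + which.min(y[(i + 1):hi])
    } else i
    idx[j] <- i
    prom[j] <- y[i] - max(y[lhs], y[rhs])
    lb[j] <- lhs; rb[j] <- rhs
  }
  tibble(index = idx, prominence = prom, left_base = lb, right_base = rb)
}

#' Per-cell signaling metrics
#'
#' A cell responds if it has at least one detected peak; it is multi-peaked
#' ("blinking") if it has more than one. Time to first peak is measured from
#' the time the cell was first detected (`valid_from`, 0 if absent).
#'
#' @param traces Tibble as in [detect_peaks()] (used for cell ids and
#'   `valid_from`).
#' @param peaks Output of [detect_peaks()].
#' @return Tibble with one row per cell: `cell_id`, `n_peaks`, `responding`,
#'   `multipeak`, `time_to_first_peak`, `mean_height_multiple`,
#'   `total_integrated_intensity`.
#' @export
summarize_cells <- function(traces, peaks) {
  cells <- traces |>
    group_by(.data$cell_id) |>
    summarise(valid_from = if ("valid_from" %in% names(traces))
      dplyr::first(.data$valid_from) else 0, .groups = "drop")
  pk <- peaks |>
    group_by(.data$cell_id) |>
    summarise(n_peaks = n(),
              # suppressWarnings: dplyr probes the expression on zero rows
              # when there are no peaks at all
              first_peak_time = suppressWarnings(min(.data$time)),
              mean_height_multiple = mean(.data$height_multiple),
              total_integrated_intensity = sum(.data$integrated_intensity),
              .groups = "drop")
  out <- left_join(cells, pk, by = "cell_id")
  out |>
    mutate(n_peaks = ifelse(is.na(.data$n_peaks), 0L, .data$n_peaks),
           responding = .data$n_peaks >= 1,
           multipeak = .data$n_peaks > 1,
           time_to_first_peak = .data$first_peak_time - .data$valid_from) |>
    select("cell_id", "n_peaks", "responding", "multipeak",
           "time_to_first_peak", "mean_height_multiple",
           "total_integrated_intensity")
}

#' Population-level calcium summary
#'
#' Fractions and means across cells: the fraction of cells with a calcium
#' response (>= 1 peak) and the fraction of responders with multiple peaks
#' (> 1), plus mean latency, height and integrated intensity over responders.
#' With zero responders the multi-peak fraction is undefined and reported as
#' `NA`, not 0.
#'
#' @param cell_summary Output of [summarize_cells()].
#' @return One-row tibble: `n_cells`, `n_responding`, `fraction_responding`,
#'   `fraction_multipeak_of_responders`, `mean_time_to_first_peak`,
#'   `mean_height_multiple`, `mean_integrated_intensity`.
#' @export
summarize_population <- function(cell_summary) {
  if (nrow(cell_summary) == 0) {
    abort("Need at least one cell.", class = "slb_input_error")
  }
  resp <- cell_summary[cell_summary$responding, ]
  tibble(
    n_cells = nrow(cell_summary),
    n_responding = nrow(resp),
    fraction_responding = nrow(resp) / nrow(cell_summary),
    fraction_multipeak_of_responders =
      if (nrow(resp)) mean(resp$multipeak) else NA_real_,
    mean_time_to_first_peak =
      if (nrow(resp)) mean(resp$time_to_first_peak) else NA_real_,
    mean_height_multiple =
      if (nrow(resp)) mean(resp$mean_height_multiple) else NA_real_,
    mean_integrated_intensity =
      if (nrow(resp)) mean(resp$total_integrated_intensity) else NA_real_
  )
}
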