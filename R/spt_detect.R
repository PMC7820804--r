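# particle detection and nearest-neighbor linking. Positions are in pixels at
# this layer (origin = center of the top-left pixel, x right, y down);
# conversion to um happens in link_tracks() via `pixel_size`.

#' Detect fluorescent particles in a single frame
#'
#' Finds local maxima above an intensity threshold and refines each candidate
#' by least-squares fitting a 2D Gaussian (amplitude, center, common width,
#' offset) in a window around the maximum, falling back to an intensity
#' centroid if the fit fails. The local background and its noise are estimated
#' from the window border (median / MAD); `snr = (peak - background) / noise`.
#'
#' @param frame Numeric matrix `[y, x]`.
#' @param min_intensity Detection threshold on background-subtracted peak
#'   intensity; default `5 * mad(frame)` above the median.
#' @param psf_sigma_guess Expected PSF sigma, pixels; sets the fit window
#'   (half-width `ceiling(3 * psf_sigma_guess)`) and the minimum separation
#'   between maxima.
#' @return Tibble with `x`, `y` (subpixel, pixels), `intensity` (fitted
#'   amplitude), `background`, `snr`. Zero rows if nothing is found.
#' @export
detect_particles <- function(frame, min_intensity = NULL,
                             psf_sigma_guess = 1.3) {
  check_matrix(frame, "frame")
  ny <- nrow(frame); nx <- ncol(frame)
  bg_global <- median(frame)
  noise_global <- max(mad(frame), 1e-12)
  if (is.null(min_intensity)) min_intensity <- 5 * noise_global
  half <- max(2L, as.integer(ceiling(3 * psf_sigma_guess)))

  # local maxima: strictly greater than the 8-neighborhood (ties broken by
  # scan order), above threshold
  cand <- which(frame - bg_global >= min_intensity, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty_localizations())
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rs <- max(1, r - 1):min(ny, r + 1)
    cs <- max(1, c - 1):min(nx, c + 1)
    frame[r, c] >= max(frame[rs, cs])   # plateau duplicates pruned below
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_localizations())
  # enforce minimum separation: keep the brighter of any close pair
  o <- order(frame[cand], decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  sel <- rep(TRUE, nrow(cand))
  min_sep <- 2 * psf_sigma_guess
  for (i in seq_len(nrow(cand))) {
    if (!sel[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
      sel[j[d2 < min_sep^2]] <- FALSE
    }
  }
  cand <- cand[sel, , drop = FALSE]

  fits <- lapply(seq_len(nrow(cand)), function(i) {
    refine_spot(frame, cand[i, 1], cand[i, 2], half, psf_sigma_guess)
  })
  out <- list_rbind(fits)
  out[order(out$y, out$x), ]
}

empty_localizations <- function() {
  tibble(x = numeric(), y = numeric(), intensity = numeric(),
         background = numeric(), snr = numeric())
}

# Gaussian refinement of one candidate maximum at matrix row r, col c
refine_spot <- function(frame, r, c, half, sigma0) {
  r <- as.integer(unname(r)); c <- as.integer(unname(c))
  ny <- nrow(frame); nx <- ncol(frame)
  rs <- max(1, r - half):min(ny, r + half)
  cs <- max(1, c - half):min(nx, c + half)
  win <- frame[rs, cs]
  # border statistics for background and noise
  border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
  bg <- median(border)
  noise <- max(mad(border), 1e-12)
  xs <- rep(cs - 1, each = length(rs))   # x = column - 1
  ys <- rep(rs - 1, times = length(cs))  # y = row - 1
  vals <- as.vector(win)
  amp0 <- frame[r, c] - bg
  df <- data.frame(v = vals, x = xs, y = ys)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b + a * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)),
      data = df,
      start = list(a = amp0, x0 = c - 1, y0 = r - 1, s = sigma0, b = bg),
      lower = c(a = 0, x0 = min(xs), y0 = min(ys), s = 0.3, b = -Inf),
      upper = c(a = Inf, x0 = max(xs), y0 = max(ys), s = 4 * sigma0, b = Inf),
      control = nls.control(maxiter = 100, warnOnly = TRUE)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    p <- coef(fit)
    tibble(x = unname(p["x0"]), y = unname(p["y0"]),
           intensity = unname(p["a"]), background = unname(p["b"]),
           snr = unname(p["a"]) / noise)
  } else {
    w <- pmax(vals - bg, 0)
    tibble(x = sum(w * xs) / sum(w), y = sum(w * ys) / sum(w),
           intensity = amp0, background = bg, snr = amp0 / noise)
  }
}

#' Detect particles in every frame of a stack
#'
#' Applies [detect_particles()] to each frame and returns one table of
#' localizations with a `frame` column.
#'
#' @param stack Numeric array `[y, x, frame]`.
#' @inheritParams detect_particles
#' @return Tibble with `frame`, `x`, `y`, `intensity`, `background`, `snr`.
#' @export
detect_particles_stack <- function(stack, min_intensity = NULL,
                                   psf_sigma_guess = 1.3) {
  n <- dim(stack)[3]
  list_rbind(lapply(seq_len(n), function(k) {
    loc <- detect_particles(stack[, , k], min_intensity, psf_sigma_guess)
    if (nrow(loc)) mutate(loc, frame = k, .before = 1) else
      mutate(loc, frame = integer())
  }))
}

#' Link per-frame localizations into tracks
#'
#' Greedy nearest-neighbor linking between consecutive frames: candidate pairs
#' (track end in frame t, detection in frame t+1) within `max_displacement`
#' are linked in order of increasing distance (ties broken by lowest particle
#' id), each end and each detection used at most once. Unlinked detections
#' start new tracks; there is no gap closing, so a missed detection terminates
#' a track.
#'
#' @param localizations Tibble with `frame`, `x`, `y` in pixels (e.g. from
#'   [detect_particles_stack()]) plus any extra columns, which are carried
#'   through.
#' @param max_displacement Maximum allowed per-frame movement, um.
#' @param pixel_size um per pixel; output positions are converted to um.
#' @param frame_interval s between frames (recorded as an attribute).
#' @return Tibble with `particle_id`, `frame`, `x`, `y` (um) and carried
#'   columns, ordered by particle then frame.
#' @export
link_tracks <- function(localizations, max_displacement, pixel_size = 1,
                        frame_interval = 1) {
  check_number(max_displacement, "max_displacement", lower = 0,
               allow_equal_lower = FALSE)
  check_number(pixel_size, "pixel_size", lower = 0, allow_equal_lower = FALSE)
  loc <- as_tibble(localizations)
  if (!all(c("frame", "x", "y") %in% names(loc))) {
    abort("`localizations` needs columns frame, x, y.",
          class = "slb_input_error")
  }
  loc$x <- loc$x * pixel_size
  loc$y <- loc$y * pixel_size
  loc <- loc[order(loc$frame), ]
  frames <- sort(unique(loc$frame))
  loc$particle_id <- NA_integer_
  next_id <- 1L
  idx_by_frame <- split(seq_len(nrow(loc)), loc$frame)

  prev_idx <- integer()
  for (fi in seq_along(frames)) {
    cur_idx <- idx_by_frame[[as.character(frames[fi])]]
    consecutive <- fi > 1 && frames[fi] == frames[fi - 1] + 1
    if (consecutive && length(prev_idx) && length(cur_idx)) {
      d <- outer(loc$x[prev_idx], loc$x[cur_idx], "-")^2 +
        outer(loc$y[prev_idx], loc$y[cur_idx], "-")^2
      d[d > max_displacement^2] <- NA
      # greedy: repeatedly take the global closest admissible pair
      repeat {
        if (all(is.na(d))) break
        best <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)
        if (nrow(best) > 1) {   # tie-break: lowest existing particle id
          ids <- loc$particle_id[prev_idx[best[, 1]]]
          best <- best[order(ids), , drop = FALSE]
        }
        pi <- best[1, 1]; ci <- best[1, 2]
        loc$particle_id[cur_idx[ci]] <- loc$particle_id[prev_idx[pi]]
        d[pi, ] <- NA
        d[, ci] <- NA
      }
    }
    new <- cur_idx[is.na(loc$particle_id[cur_idx])]
    if (length(new)) {
      loc$particle_id[new] <- seq(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
  }
  out <- loc[order(loc$particle_id, loc$frame),
             c("particle_id", setdiff(names(loc), "particle_id"))]
  attr(out, "frame_interval") <- frame_interval
  attr(out, "pixel_size") <- pixel_size
  out
}
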