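# synthetic fluorescence imaging: Gaussian-spot TIRF frames and disk-shaped
# cells for calcium movies; frames are matrices indexed [row = y, col = x],
# origin at the center of the top-left pixel, x right, y down.

#' Render single-molecule image stacks from tracks
#'
#' Draws every localization as an integrated 2D Gaussian spot on a constant
#' background and applies Poisson photon (shot) noise, emulating EMCCD TIRF
#' movies at a controllable signal-to-noise ratio. Track coordinates (um) are
#' converted to pixels with `pixel_size`; tracks can be offset so they fit in
#' the field of view.
#'
#' @param tracks Tibble with `particle_id`, `frame`, `x`, `y` (um), e.g. from
#'   [simulate_tracks()].
#' @param image_size `c(width, height)` in pixels.
#' @param pixel_size um per pixel.
#' @param psf_sigma Gaussian PSF standard deviation, pixels.
#' @param photons_per_spot Expected photons integrated over one spot.
#' @param background_level Expected background photons per pixel.
#' @param offset `c(x, y)` um added to all positions before rendering,
#'   `"center"` (default) to center the track cloud in the field, or `c(0, 0)`
#'   equivalent `"none"`.
#' @param noise `"poisson"` (default) or `"none"` for the noiseless expected
#'   image.
#' @param seed Integer seed.
#' @return A numeric array `[y, x, frame]` of photon counts, with the rendered
#'   ground-truth positions (pixel units) attached as `ground_truth`.
#'   Spots whose centers fall outside the field are clipped with a warning.
#' @export
render_image_stack <- function(tracks, image_size = c(64, 64), pixel_size = 0.1,
                               psf_sigma = 1.3, photons_per_spot = 500,
                               background_level = 10, offset = "center",
                               noise = c("poisson", "none"), seed = NULL) {
  noise <- match.arg(noise)
  check_number(pixel_size, "pixel_size", lower = 0, allow_equal_lower = FALSE)
  check_number(psf_sigma, "psf_sigma", lower = 0, allow_equal_lower = FALSE)
  nx <- as.integer(image_size[1]); ny <- as.integer(image_size[2])

  px <- tracks$x / pixel_size
  py <- tracks$y / pixel_size
  if (identical(offset, "center")) {
    off <- c((nx - 1) / 2 - mean(range(px)), (ny - 1) / 2 - mean(range(py)))
  } else if (identical(offset, "none")) {
    off <- c(0, 0)
  } else {
    off <- as.numeric(offset) / pixel_size
  }
  px <- px + off[1]; py <- py + off[2]

  inside <- px >= -0.5 & px <= nx - 0.5 & py >= -0.5 & py <= ny - 0.5
  if (any(!inside)) {
    warn(sprintf("%d localization(s) fall outside the field of view; clipped.",
                 sum(!inside)))
  }

  frames <- sort(unique(tracks$frame))
  truth <- tibble(particle_id = tracks$particle_id, frame = tracks$frame,
                  x_px = px, y_px = py, rendered = inside)

  stack <- array(background_level, dim = c(ny, nx, length(frames)))
  half <- ceiling(4 * psf_sigma)
  for (k in seq_along(frames)) {
    sel <- which(tracks$frame == frames[k] & inside)
    if (!length(sel)) next
    img <- stack[, , k]
    for (i in sel) {
      cx <- px[i]; cy <- py[i]
      x0 <- max(0L, floor(cx) - half); x1 <- min(nx - 1L, floor(cx) + half)
      y0 <- max(0L, floor(cy) - half); y1 <- min(ny - 1L, floor(cy) + half)
      xs <- x0:x1; ys <- y0:y1
      # integrated Gaussian over each pixel via error-function differences
      fx <- pnorm(xs + 0.5, cx, psf_sigma) - pnorm(xs - 0.5, cx, psf_sigma)
      fy <- pnorm(ys + 0.5, cy, psf_sigma) - pnorm(ys - 0.5, cy, psf_sigma)
      img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] +
        photons_per_spot * outer(fy, fx)
    }
    stack[, , k] <- img
  }
  if (noise == "poisson") {
    stack <- with_seed(seed, {
      array(rpois(length(stack), lambda = stack), dim = dim(stack))
    })
  }
  attr(stack, "ground_truth") <- list(
    positions = truth, pixel_size = pixel_size, psf_sigma = psf_sigma,
    photons_per_spot = photons_per_spot, background_level = background_level,
    offset_px = off
  )
  stack
}

#' Render a calcium time-lapse from per-cell intensity traces
#'
#' Places each cell as a uniform disk at a fixed position; the disk intensity
#' in each frame equals the cell's trace value at that time. Gaussian read
#' noise is added per pixel. Used to exercise the segmentation/tracking stage
#' end to end against known traces.
#'
#' @param traces Tibble with `cell_id`, `time`, `intensity`, e.g. from
#'   [simulate_calcium_population()].
#' @param image_size `c(width, height)` pixels.
#' @param cell_radius Disk radius, pixels.
#' @param positions Optional tibble `cell_id`, `x`, `y` (pixel centers); by
#'   default cells are laid out on a grid with at least `3 * cell_radius`
#'   spacing.
#' @param background_level Constant background, a.u.
#' @param noise_sd Gaussian pixel noise sd, a.u.
#' @param seed Integer seed.
#' @return Numeric array `[y, x, frame]` with `ground_truth` attribute holding
#'   the positions used.
#' @export
render_calcium_stack <- function(traces, image_size = c(128, 128),
                                 cell_radius = 5, positions = NULL,
                                 background_level = 10, noise_sd = 1,
                                 seed = NULL) {
  ids <- sort(unique(traces$cell_id))
  times <- sort(unique(traces$time))
  nx <- as.integer(image_size[1]); ny <- as.integer(image_size[2])
  if (is.null(positions)) {
    spacing <- ceiling(3 * cell_radius) + 2L
    per_row <- max(1L, (nx - spacing) %/% spacing)
    gx <- spacing * (((seq_along(ids) - 1L) %% per_row) + 1L)
    gy <- spacing * (((seq_along(ids) - 1L) %/% per_row) + 1L)
    if (max(gy) > ny - cell_radius) {
      abort("Too many cells for the requested image size.",
            class = "slb_parameter_error")
    }
    positions <- tibble(cell_id = ids, x = gx, y = gy)
  }
  xs <- matrix(rep(seq_len(nx) - 1L, each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny) - 1L, times = nx), ny, nx)
  masks <- lapply(seq_along(ids), function(i) {
    (xs - positions$x[i])^2 + (ys - positions$y[i])^2 <= cell_radius^2
  })
  ti <- split(traces, traces$cell_id)
  stack <- array(background_level, dim = c(ny, nx, length(times)))
  for (k in seq_along(times)) {
    img <- stack[, , k]
    for (i in seq_along(ids)) {
      tr <- ti[[as.character(ids[i])]]
      v <- tr$intensity[match(times[k], tr$time)]
      if (!is.na(v)) img[masks[[i]]] <- v
    }
    stack[, , k] <- img
  }
  if (noise_sd > 0) {
    stack <- with_seed(seed, {
      stack + array(rnorm(length(stack), sd = noise_sd), dim = dim(stack))
    })
  }
  attr(stack, "ground_truth") <- list(positions = positions,
                                      cell_radius = cell_radius,
                                      background_level = background_level)
  stack
}
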