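# two-channel receptor-exclusion quantification

#' Average an image stack over time
#'
#' @param stack Numeric array `[y, x, frame]` or a single matrix.
#' @return Matrix of pixel-wise means.
#' @export
average_stack <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3 || dim(stack)[3] < 1) {
    abort("`stack` must be a [y, x, frame] array with >= 1 frame.",
          class = "slb_input_error")
  }
  apply(stack, c(1, 2), mean)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale morphological opening of the
#' image with a flat disk structuring element of the given radius (the
#' standard fast realization of the rolling-ball filter: any feature narrower
#' than the ball is removed from the background) and subtracts it. Negative
#' results are clipped to zero.
#'
#' @param image Numeric matrix.
#' @param radius Ball/disk radius, pixels (default 50).
#' @param return_background If `TRUE`, return the estimated background rather
#'   than the subtracted image.
#' @return Matrix: the background-subtracted image (or the background).
#' @export
rolling_ball_background <- function(image, radius = 50,
                                    return_background = FALSE) {
  check_matrix(image)
  check_number(radius, "radius", lower = 1)
  if (2 * radius + 1 >= min(dim(image))) {
    abort("`radius` must be smaller than half the image size.",
          class = "slb_parameter_error")
  }
  brush <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  # EBImage grayscale morphology operates on [0, 1]; rescale (min/max commute
  # with a positive affine map, so the opening is unaffected)
  rng <- range(image)
  if (diff(rng) == 0) {
    bg <- image                       # opening of a constant is the constant
  } else {
    scaled <- (image - rng[1]) / diff(rng)
    op <- EBImage::imageData(EBImage::dilate(EBImage::erode(
      EBImage::Image(scaled), brush), brush))
    bg <- matrix(op, nrow(image), ncol(image)) * diff(rng) + rng[1]
  }
  if (return_background) return(bg)
  pmax(image - bg, 0)
}

#' Otsu threshold (256 equal-width bins)
#'
#' Computes the threshold that maximizes the between-class variance of the
#' intensity histogram, built from `n_bins` equal-width bins spanning the
#' image range. The returned threshold is the upper edge of the chosen bin;
#' pixels strictly above it form the foreground.
#'
#' @param image Numeric matrix (or vector of intensities).
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (numeric scalar), with the maximizing bin index as
#'   attribute `bin`.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) {
    abort("Degenerate histogram: image is constant.",
          class = "slb_degenerate_error")
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)                       # class 0 = bins 1..k
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  # between-class variance for threshold after bin k (k = 1..n_bins-1)
  k <- seq_len(n_bins - 1)
  valid <- w0[k] > 0 & w0[k] < 1
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (mu_t * w0[k][valid] - mu0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  best <- which.max(bcv)
  thr <- edges[best + 1]
  attr(thr, "bin") <- best
  thr
}

#' Otsu foreground mask
#'
#' @inheritParams otsu_threshold
#' @return Logical matrix, `TRUE` above the Otsu threshold; the threshold is
#'   attached as attribute `threshold`.
#' @export
otsu_mask <- function(image, n_bins = 256) {
  check_matrix(image)
  thr <- otsu_threshold(image, n_bins)
  m <- image > as.numeric(thr)
  attr(m, "threshold") <- as.numeric(thr)
  m
}

#' Quantify exclusion of a probe channel from a contact
#'
#' Builds the contact mask by Otsu-thresholding the adhesion-marker channel
#' and the cell mask as the union of that mask with the Otsu mask of the probe
#' channel, then compares mean probe intensity inside the contact with the
#' mean over the rest of the cell footprint:
#' \deqn{\mathrm{Exclusion} = 1 - \overline{I_{in}} / \overline{I_{out}}.}
#' Negative values (enrichment) are reported, not clamped.
#'
#' @param channel_contact Adhesion-marker image (matrix), averaged and
#'   background-subtracted (see [average_stack()],
#'   [rolling_ball_background()]).
#' @param channel_probe Probe (e.g. CD45) image, same size and preprocessing.
#'   Alternatively pass a `contact_image` from [simulate_contact_image()] as
#'   the first argument.
#' @param min_object_px Optional small-object cleanup: connected foreground
#'   components smaller than this are dropped from each mask (0 = keep all,
#'   the default).
#' @return An `exclusion_result`: list with `exclusion`, `mean_in`,
#'   `mean_out`, `contact_mask`, `cell_mask`, `n_in`, `n_out`.
#' @export
compute_exclusion <- function(channel_contact, channel_probe = NULL,
                              min_object_px = 0) {
  if (inherits(channel_contact, "contact_image")) {
    channel_probe <- channel_contact$channel_probe
    channel_contact <- channel_contact$channel_contact
  }
  check_matrix(channel_contact, "channel_contact")
  check_matrix(channel_probe, "channel_probe")
  if (!all(dim(channel_contact) == dim(channel_probe))) {
    abort("Channels must have identical dimensions.",
          class = "slb_input_error")
  }
  contact_mask <- otsu_mask(channel_contact)
  probe_mask <- otsu_mask(channel_probe)
  if (min_object_px > 0) {
    contact_mask <- drop_small_objects(contact_mask, min_object_px)
    probe_mask <- drop_small_objects(probe_mask, min_object_px)
  }
  cell_mask <- contact_mask | probe_mask
  outside <- cell_mask & !contact_mask
  if (!any(contact_mask)) {
    abort("Empty contact mask.", class = "slb_degenerate_error")
  }
  if (!any(outside)) {
    abort("No cell pixels outside the contact.",
          class = "slb_degenerate_error")
  }
  mean_in <- mean(channel_probe[contact_mask])
  mean_out <- mean(channel_probe[outside])
  if (mean_out <= 0) {
    abort("Mean probe intensity outside the contact is not positive.",
          class = "slb_degenerate_error")
  }
  structure(
    list(exclusion = 1 - mean_in / mean_out, mean_in = mean_in,
         mean_out = mean_out, contact_mask = contact_mask,
         cell_mask = cell_mask, n_in = sum(contact_mask),
         n_out = sum(outside)),
    class = "exclusion_result"
  )
}

drop_small_objects <- function(mask, min_px) {
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat(sprintf(
    "Exclusion = %.3f (mean in = %.3g over %d px, mean out = %.3g over %d px)\n",
    x$exclusion, x$mean_in, x$n_in, x$mean_out, x$n_out))
  invisible(x)
}
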