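#' Simulate a two-channel cell-contact image
#'
#' Emulates registered TIRF images of a cell contact on a bilayer: channel 1
#' carries an adhesion marker (e.g. rCD2) that is enriched inside the contact,
#' channel 2 a large membrane protein (e.g. the phosphatase CD45) whose
#' intensity inside the contact is multiplied by a depletion factor. The cell
#' footprint is an ellipse containing a disk-shaped contact. An optional
#' linear background gradient and Gaussian noise are added to both channels.
#' By construction, channel-2 exclusion computed on the ground-truth masks
#' equals `1 - depletion_factor` when noise and gradient are zero.
#'
#' @param image_size `c(width, height)` pixels.
#' @param contact Disk `list(cx, cy, r)` in pixels; default centered, radius
#'   1/6 of the width.
#' @param cell Ellipse `list(cx, cy, rx, ry)`; default centered, spanning ~70%
#'   of the field.
#' @param enrichment_factor Channel-1 multiplier inside the contact (>= 1).
#' @param depletion_factor Channel-2 multiplier inside the contact, in
#'   `[0, 1]`.
#' @param ch1_level Channel-1 intensity on the cell outside the contact, a.u.
#' @param ch2_level Channel-2 intensity on the cell outside the contact, a.u.
#' @param background Off-cell intensity in both channels, a.u.
#' @param gradient Linear background slope added to both channels, a.u./pixel
#'   along x.
#' @param noise_sd Gaussian noise sd, a.u.
#' @param seed Integer seed.
#' @return A `contact_image`: list with matrices `channel_contact`,
#'   `channel_probe`, logical ground-truth `contact_mask` and `cell_mask`, and
#'   the generator parameters in `params`.
#' @export
simulate_contact_image <- function(image_size = c(128, 128), contact = NULL,
                                   cell = NULL, enrichment_factor = 3,
                                   depletion_factor = 0.5, ch1_level = 100,
                                   ch2_level = 200, background = 5,
                                   gradient = 0, noise_sd = 0, seed = NULL) {
  check_number(enrichment_factor, "enrichment_factor", lower = 1)
  check_number(depletion_factor, "depletion_factor", lower = 0, upper = 1)
  nx <- as.integer(image_size[1]); ny <- as.integer(image_size[2])
  if (is.null(contact)) contact <- list(cx = (nx - 1) / 2, cy = (ny - 1) / 2,
                                        r = nx / 6)
  if (is.null(cell)) cell <- list(cx = (nx - 1) / 2, cy = (ny - 1) / 2,
                                  rx = 0.35 * nx, ry = 0.35 * ny)
  xs <- matrix(rep(seq_len(nx) - 1L, each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny) - 1L, times = nx), ny, nx)
  contact_mask <- (xs - contact$cx)^2 + (ys - contact$cy)^2 <= contact$r^2
  cell_mask <- ((xs - cell$cx) / cell$rx)^2 + ((ys - cell$cy) / cell$ry)^2 <= 1
  if (any(contact_mask & !cell_mask)) {
    abort("Contact region must lie inside the cell footprint.",
          class = "slb_parameter_error")
  }
  ch1 <- matrix(background, ny, nx)
  ch1[cell_mask] <- ch1_level
  ch1[contact_mask] <- ch1_level * enrichment_factor
  ch2 <- matrix(background, ny, nx)
  ch2[cell_mask] <- ch2_level
  ch2[contact_mask] <- ch2_level * depletion_factor
  if (gradient != 0) {
    ch1 <- ch1 + gradient * xs
    ch2 <- ch2 + gradient * xs
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, list(matrix(rnorm(ny * nx, sd = noise_sd), ny, nx),
                                  matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)))
    ch1 <- pmax(ch1 + noise[[1]], 0)
    ch2 <- pmax(ch2 + noise[[2]], 0)
  }
  structure(
    list(channel_contact = ch1, channel_probe = ch2,
         contact_mask = contact_mask, cell_mask = cell_mask,
         params = list(contact = contact, cell = cell,
                       enrichment_factor = enrichment_factor,
                       depletion_factor = depletion_factor,
                       ch1_level = ch1_level, ch2_level = ch2_level,
                       background = background, gradient = gradient,
                       noise_sd = noise_sd, seed = seed)),
    class = "contact_image"
  )
}
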