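# shared fixtures, built in code at test time

sphere_indenter <- function(r = 18.5) list(type = "sphere", radius_um = r)
pyramid_indenter <- function(a = 20) list(type = "pyramid", half_angle_deg = a)

# standard push-through fixture: pyramidal tip, stiff (1 MPa) substrate,
# 0.5 nm sampling, 0.02 nN force noise
make_pushthrough_curve <- function(z_jump_nm = 3.9, breakthrough_force_nn = 5,
                                   noise_sd_nn = 0.02, seed = NULL, ...) {
  simulate_force_curve(
    young_modulus = 1e6, poisson_ratio = 0.5, indenter = pyramid_indenter(),
    contact_point_um = 1, z_range_um = 1.2, sampling_step_nm = 0.5,
    z_jump_nm = z_jump_nm, breakthrough_force_nn = breakthrough_force_nn,
    noise_sd_nn = noise_sd_nn, seed = seed, ...)
}

make_smooth_curve <- function(noise_sd_nn = 0.02, seed = NULL) {
  simulate_force_curve(
    young_modulus = 1e6, poisson_ratio = 0.5, indenter = pyramid_indenter(),
    contact_point_um = 1, z_range_um = 1.2, sampling_step_nm = 0.5,
    noise_sd_nn = noise_sd_nn, seed = seed)
}

# well-separated tracks laid out on a grid, for imaging-pipeline tests
make_grid_tracks <- function(n_side = 3, track_length = 12, d_coef = 0.08,
                             frame_interval = 0.02, seed = 2, spacing = 2,
                             origin = 1.5) {
  trk <- simulate_tracks(n_side^2, track_length, d_coef = d_coef,
                         sigma_loc = 0, frame_interval = frame_interval,
                         seed = seed)
  offs <- expand.grid(ox = origin + spacing * (seq_len(n_side) - 1),
                      oy = origin + spacing * (seq_len(n_side) - 1))
  trk$x <- trk$x + offs$ox[trk$particle_id]
  trk$y <- trk$y + offs$oy[trk$particle_id]
  trk
}

# tracks tibble from a matrix of per-frame positions (one particle per column
# pair), for constructed linking/filtering cases
manual_track <- function(particle_id, x, y, frames = seq_along(x)) {
  tibble::tibble(particle_id = particle_id, frame = frames, x = x, y = y)
}

# independent brute-force Otsu: exhaustively evaluate the between-class
# variance of every candidate split of the 256-bin histogram, computing the
# class weights and means by direct summation (Otsu's statistic is defined on
# the histogram, with bins represented by their midpoints)
otsu_brute_force <- function(v, n_bins = 256) {
  v <- as.numeric(v)
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), n_bins)
  counts <- vapply(seq_len(n_bins), function(b) sum(bin == b), numeric(1))
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  bcv <- vapply(seq_len(n_bins - 1), function(k) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1):n_bins])
    if (n0 == 0 || n1 == 0) return(-Inf)
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    (n0 / length(v)) * (n1 / length(v)) * (mu0 - mu1)^2
  }, numeric(1))
  edges[which.max(bcv) + 1]
}

# independent brute-force grayscale opening (erosion then dilation) with a
# flat disk, plain R loops -- oracle for rolling_ball_background. The
# structuring element is supplied so the same disk definition is compared;
# the morphology itself is computed independently.
opening_brute_force <- function(img, radius, brush = NULL) {
  ny <- nrow(img); nx <- ncol(img)
  if (is.null(brush)) {
    offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
    offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2 + radius / 2, ]
  } else {
    w <- which(brush > 0, arr.ind = TRUE)
    c0 <- (nrow(brush) + 1) / 2
    offs <- data.frame(dy = w[, 1] - c0, dx = w[, 2] - c0)
  }
  sweep_one <- function(m, f) {
    out <- matrix(NA_real_, ny, nx)
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      ii <- i + offs$dy; jj <- j + offs$dx
      ok <- ii >= 1 & ii <= ny & jj >= 1 & jj <= nx
      out[i, j] <- f(m[cbind(ii[ok], jj[ok])])
    }
    out
  }
  sweep_one(sweep_one(img, min), max)
}
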