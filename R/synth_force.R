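# synthetic AFM approach curves: Hertzian contact with optional bilayer
# push-through discontinuities. Units at the interface: z in um, force in nN,
# z-jump in nm, modulus in Pa.

#' Hertz/Sneddon contact force
#'
#' Indentation force for an elastic half-space. Spherical indenter (radius R):
#' \deqn{F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}}
#' Pyramidal/conical indenter (half-angle \eqn{\alpha}):
#' \deqn{F = \frac{2}{\pi}\,\frac{E}{1-\nu^2}\,\tan(\alpha)\,\delta^{2}}
#'
#' @param delta_um Indentation depth(s), um; negative values give zero force.
#' @param young_modulus Young's modulus E, Pa.
#' @param poisson_ratio Poisson ratio (0.5 = incompressible, the default for
#'   PDMS-like elastomers).
#' @param indenter `list(type = "sphere", radius_um = ...)` or
#'   `list(type = "pyramid", half_angle_deg = ...)`.
#' @return Force in nN.
#' @examples
#' hertz_force(1, 3000, 0.5, list(type = "sphere", radius_um = 10)) # ~16.9 nN
#' @export
hertz_force <- function(delta_um, young_modulus, poisson_ratio = 0.5,
                        indenter = list(type = "sphere", radius_um = 18.5)) {
  check_number(young_modulus, "young_modulus", lower = 0,
               allow_equal_lower = FALSE)
  check_number(poisson_ratio, "poisson_ratio", lower = 0, upper = 0.5)
  d <- pmax(delta_um, 0) * 1e-6                       # m
  e_eff <- young_modulus / (1 - poisson_ratio^2)      # Pa
  f_newton <- switch(indenter$type,
    sphere = {
      r <- indenter$radius_um * 1e-6
      (4 / 3) * e_eff * sqrt(r) * d^1.5
    },
    pyramid = {
      alpha <- indenter$half_angle_deg * pi / 180
      (2 / pi) * e_eff * tan(alpha) * d^2
    },
    abort("`indenter$type` must be \"sphere\" or \"pyramid\".",
          class = "slb_parameter_error")
  )
  f_newton * 1e9                                      # nN
}

#' Simulate an AFM approach force curve
#'
#' Builds an approach segment: zero force before the contact point, then the
#' Hertz/Sneddon law for the stated indenter. If `z_jump_nm > 0`, each time
#' the force first reaches the corresponding `breakthrough_force_nn` the tip
#' penetrates a bilayer: the force stays at the breakthrough level while the
#' piezo advances by the z-jump, after which the contact law resumes shifted
#' toward the substrate (same substrate stiffness, so the slopes before and
#' after the event match). Several stacked bilayers can be simulated by
#' passing vectors.
#'
#' @param young_modulus Substrate Young's modulus, Pa.
#' @param poisson_ratio Poisson ratio.
#' @param indenter See [hertz_force()].
#' @param contact_point_um Piezo position of first contact, um.
#' @param z_range_um Total sampled piezo travel, um (starting at 0).
#' @param sampling_step_nm Piezo sampling step, nm.
#' @param z_jump_nm Bilayer thickness(es), nm; 0 (default) = no push-through.
#' @param breakthrough_force_nn Force(s) at which each push-through occurs, nN.
#' @param noise_sd_nn Gaussian force noise sd, nN.
#' @param seed Integer seed.
#' @return Tibble with `z_um` (piezo extension, increasing toward the sample)
#'   and `force_nn`, plus a `ground_truth` attribute with all parameters.
#' @export
simulate_force_curve <- function(young_modulus, poisson_ratio = 0.5,
                                 indenter = list(type = "sphere",
                                                 radius_um = 18.5),
                                 contact_point_um = 1,
                                 z_range_um = 3,
                                 sampling_step_nm = 0.5,
                                 z_jump_nm = 0,
                                 breakthrough_force_nn = numeric(),
                                 noise_sd_nn = 0, seed = NULL) {
  check_number(contact_point_um, "contact_point_um", lower = 0)
  check_number(z_range_um, "z_range_um", lower = 0, allow_equal_lower = FALSE)
  if (contact_point_um >= z_range_um) {
    abort("`contact_point_um` must lie inside the sampled z range.",
          class = "slb_parameter_error")
  }
  if (any(z_jump_nm < 0)) {
    abort("`z_jump_nm` must be >= 0.", class = "slb_parameter_error")
  }
  jumps_um <- z_jump_nm[z_jump_nm > 0] * 1e-3
  forces_b <- breakthrough_force_nn
  if (length(jumps_um) != length(forces_b)) {
    abort("Each positive `z_jump_nm` needs a matching `breakthrough_force_nn`.",
          class = "slb_parameter_error")
  }
  if (length(forces_b) > 1 && any(diff(forces_b) <= 0)) {
    abort("`breakthrough_force_nn` must be increasing for stacked events.",
          class = "slb_parameter_error")
  }

  z <- seq(0, z_range_um, by = sampling_step_nm * 1e-3)
  force <- numeric(length(z))
  shift <- 0          # accumulated contact-point shift from completed events
  event_truth <- list()
  i <- 1L
  k <- 1L             # next event index
  while (i <= length(z)) {
    f <- hertz_force(z[i] - contact_point_um - shift, young_modulus,
                     poisson_ratio, indenter)
    if (k <= length(forces_b) && f >= forces_b[k]) {
      # plateau: piezo advances by the bilayer thickness at constant force
      z_start <- z[i]
      z_end <- z_start + jumps_um[k]
      while (i <= length(z) && z[i] < z_end) {
        force[i] <- forces_b[k]
        i <- i + 1L
      }
      shift <- shift + jumps_um[k]
      event_truth[[k]] <- list(z_start = z_start, z_end = z_end,
                               z_jump_nm = jumps_um[k] * 1e3,
                               breakthrough_force_nn = forces_b[k])
      k <- k + 1L
    } else {
      force[i] <- f
      i <- i + 1L
    }
  }
  if (noise_sd_nn > 0) {
    force <- with_seed(seed, force + rnorm(length(force), sd = noise_sd_nn))
  }
  out <- tibble(z_um = z, force_nn = force)
  attr(out, "ground_truth") <- list(
    young_modulus = young_modulus, poisson_ratio = poisson_ratio,
    indenter = indenter, contact_point_um = contact_point_um,
    z_jump_nm = z_jump_nm, breakthrough_force_nn = breakthrough_force_nn,
    sampling_step_nm = sampling_step_nm, noise_sd_nn = noise_sd_nn,
    events = event_truth, seed = seed
  )
  class(out) <- c("force_curve", class(out))
  out
}
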