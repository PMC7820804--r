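# broom-style tidiers for the fit objects

#' Tidy an MSD fit
#'
#' The localization-error offset is reported in all three conventions seen in
#' the literature (`sigma_loc` in um, `sigma_loc_sq` in um^2, and the raw
#' fitted intercept `offset_4sigma_sq` in um^2).
#'
#' @param x An `msd_fit` from [fit_msd()].
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` columns.
#' @method tidy msd_fit
#' @export
tidy.msd_fit <- function(x, ...) {
  tibble(
    term = c("d_coef", "sigma_loc", "sigma_loc_sq", "offset_4sigma_sq"),
    estimate = c(x$d_coef, x$sigma_loc, x$sigma_loc^2, x$offset)
  )
}

#' @rdname tidy.msd_fit
#' @method glance msd_fit
#' @export
glance.msd_fit <- function(x, ...) {
  tibble(d_coef = x$d_coef, sigma_loc = x$sigma_loc,
         n_points = x$n_points, n_tracks = x$n_tracks %||% NA_integer_,
         residual = x$residual, blur_model = x$blur_model,
         flagged = length(x$flags) > 0)
}

#' Tidy a jump-distance fit
#'
#' @param x A `jd_fit` from [jump_distance_fit()].
#' @param ... Unused.
#' @return One row per component: `component`, `fraction`, `d_coef`
#'   (fast-first).
#' @method tidy jd_fit
#' @export
tidy.jd_fit <- function(x, ...) {
  mutate(x$components, component = dplyr::row_number(), .before = 1)
}

#' @rdname tidy.jd_fit
#' @method glance jd_fit
#' @export
glance.jd_fit <- function(x, ...) {
  tibble(n_components = nrow(x$components), n_steps = x$n_steps,
         n_tracks = x$n_tracks, delta_t = x$delta_t, loglik = x$loglik,
         method = x$method, collapsed = "components_collapsed" %in% x$flags)
}

#' Tidy a FRAP fit
#'
#' @param x A `frap_fit` from [fit_axelrod()].
#' @param ... Unused.
#' @return A tibble with `term`/`estimate`, including both the Axelrod
#'   diffusion coefficient and the half-time estimate.
#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(
    term = c("d_coef", "d_halftime", "tau_d", "mobile_fraction",
             "bleach_depth", "f0", "f_inf", "beam_radius"),
    estimate = c(x$d_coef, x$d_halftime, x$tau_d, x$mobile_fraction,
                 x$bleach_depth, x$f0, x$f_inf, x$beam_radius)
  )
}

#' @rdname tidy.frap_fit
#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(d_coef = x$d_coef, mobile_fraction = x$mobile_fraction,
         tau_d = x$tau_d, residual = x$residual, n_points = x$n_points,
         flagged = length(x$flags) > 0)
}

#' Tidy a Hertz fit
#'
#' @param x A `hertz_fit` from [fit_hertz()].
#' @param ... Unused.
#' @return A tibble with `term`/`estimate` (modulus in Pa and kPa, contact
#'   point in um).
#' @method tidy hertz_fit
#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble(
    term = c("young_modulus_pa", "young_modulus_kpa", "contact_point_um"),
    estimate = c(x$young_modulus, x$young_modulus / 1e3, x$contact_point)
  )
}

#' @rdname tidy.hertz_fit
#' @method glance hertz_fit
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble(young_modulus_pa = x$young_modulus,
         contact_point_um = x$contact_point,
         poisson_ratio = x$poisson_ratio, radius_um = x$radius_um,
         n_points = x$n_points, residual = x$residual)
}

#' Tidy an exclusion result
#'
#' @param x An `exclusion_result` from [compute_exclusion()].
#' @param ... Unused.
#' @return One-row tibble with the exclusion statistic and mask statistics.
#' @method tidy exclusion_result
#' @export
tidy.exclusion_result <- function(x, ...) {
  tibble(exclusion = x$exclusion, mean_in = x$mean_in, mean_out = x$mean_out,
         n_in = x$n_in, n_out = x$n_out)
}
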