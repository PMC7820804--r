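# umbrella configuration and stage dispatch

#' Build a validated analysis configuration
#'
#' Central parameter container for the pipeline stages. Physical parameters
#' must be positive; unknown keys are rejected.
#'
#' @param pixel_size um per pixel.
#' @param frame_interval s between frames.
#' @param exposure_time Camera exposure, s.
#' @param seed Integer seed for stochastic stages.
#' @param output_directory Where [run_pipeline()] writes result tables.
#' @param spt,frap,calcium,exclusion,afm,synth Optional named lists of
#'   stage-specific parameters, passed through to the stage functions.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(pixel_size = 0.1, frame_interval = 0.01,
                            exposure_time = 0.01, seed = 1L,
                            output_directory = NULL,
                            spt = list(), frap = list(), calcium = list(),
                            exclusion = list(), afm = list(), synth = list()) {
  check_number(pixel_size, "pixel_size", lower = 0, allow_equal_lower = FALSE)
  check_number(frame_interval, "frame_interval", lower = 0,
               allow_equal_lower = FALSE)
  check_number(exposure_time, "exposure_time", lower = 0,
               allow_equal_lower = FALSE)
  cfg <- list(pixel_size = pixel_size, frame_interval = frame_interval,
              exposure_time = exposure_time, seed = as.integer(seed),
              output_directory = output_directory,
              spt = spt, frap = frap, calcium = calcium,
              exclusion = exclusion, afm = afm, synth = synth)
  class(cfg) <- "analysis_config"
  cfg
}

#' Load an analysis configuration from JSON
#'
#' Unknown keys are rejected with an error naming the key.
#'
#' @param path Path to a JSON file whose fields match [analysis_config()]
#'   arguments.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "slb_config_error")
  }
  do.call(analysis_config, raw)
}

#' Run one pipeline stage
#'
#' Dispatches to the stage implementation with the config's parameters and
#' returns a result table whose attributes record the resolved parameters
#' (including seed and package version), so every output is reproducible from
#' the config alone.
#'
#' Stages and their expected `inputs`:
#' * `"synth"` — `inputs$what` in `"tracks"`, `"frap"`, `"calcium"`,
#'   `"force"`; generator parameters come from `config$synth`.
#' * `"spt"` — `inputs$stack` (array) or `inputs$tracks` (tibble in um);
#'   runs detect/link/filter/MSD-fit and a jump-distance fit.
#' * `"frap"` — `inputs$trace` (raw trace tibble) or a `frap_trace`, plus
#'   `beam_radius` in `config$frap`.
#' * `"calcium"` — `inputs$stack` or `inputs$traces`.
#' * `"exclusion"` — `inputs$channel_contact`, `inputs$channel_probe`
#'   (matrices or stacks).
#' * `"afm"` — `inputs$curve` (force-curve tibble); fits Hertz and detects
#'   push-through events (set `config$afm$radius_um`).
#'
#' @param config An [analysis_config()].
#' @param stage One of `"synth"`, `"spt"`, `"frap"`, `"calcium"`,
#'   `"exclusion"`, `"afm"`.
#' @param inputs Named list of stage inputs (see Details).
#' @return A tibble of stage results with a `params` attribute; if
#'   `config$output_directory` is set, also written there via
#'   [write_result_table()].
#' @export
run_pipeline <- function(config, stage, inputs = list()) {
  if (!inherits(config, "analysis_config")) {
    abort("`config` must come from analysis_config().",
          class = "slb_config_error")
  }
  stages <- c("synth", "spt", "frap", "calcium", "exclusion", "afm")
  if (!is.character(stage) || length(stage) != 1 || !stage %in% stages) {
    abort(sprintf("Unknown stage %s; expected one of %s.",
                  deparse(substitute(stage)), paste(stages, collapse = ", ")),
          class = "slb_config_error")
  }
  res <- switch(stage,
    synth = stage_synth(config, inputs),
    spt = stage_spt(config, inputs),
    frap = stage_frap(config, inputs),
    calcium = stage_calcium(config, inputs),
    exclusion = stage_exclusion(config, inputs),
    afm = stage_afm(config, inputs)
  )
  params <- c(config[c("pixel_size", "frame_interval", "exposure_time",
                       "seed")],
              config[[stage]], list(stage = stage))
  attr(res, "params") <- params
  if (!is.null(config$output_directory)) {
    dir.create(config$output_directory, showWarnings = FALSE,
               recursive = TRUE)
    write_result_table(res, file.path(config$output_directory,
                                      paste0(stage, "_results.tsv")), params)
  }
  res
}

stage_synth <- function(config, inputs) {
  what <- inputs$what %||% "tracks"
  p <- config$synth
  switch(what,
    tracks = do.call(simulate_tracks, modifyList(
      list(n_tracks = 100, track_length = 20, d_coef = 1,
           frame_interval = config$frame_interval, seed = config$seed), p)),
    frap = do.call(simulate_frap_curve, modifyList(
      list(timepoints = 0:180, bleach_depth = 1, tau_d = 2,
           mobile_fraction = 0.9, f0 = 0.3, noise_sd = 0.01,
           seed = config$seed), p)),
    calcium = do.call(simulate_calcium_population, modifyList(
      list(n_cells = 100, seed = config$seed), p)),
    force = do.call(simulate_force_curve, modifyList(
      list(young_modulus = 4590, seed = config$seed), p)),
    abort(sprintf("Unknown synth output `%s`.", what),
          class = "slb_config_error")
  )
}

stage_spt <- function(config, inputs) {
  p <- config$spt
  tracks <- if (!is.null(inputs$tracks)) {
    inputs$tracks
  } else if (!is.null(inputs$stack)) {
    loc <- detect_particles_stack(inputs$stack,
                                  min_intensity = p$min_intensity,
                                  psf_sigma_guess = p$psf_sigma %||% 1.3)
    link_tracks(loc, max_displacement = p$max_displacement %||% 0.8,
                pixel_size = config$pixel_size,
                frame_interval = config$frame_interval)
  } else {
    abort("spt stage needs `inputs$stack` or `inputs$tracks`.",
          class = "slb_config_error")
  }
  tracks <- filter_tracks(tracks, min_length = p$min_track_length %||% 6)
  msd <- compute_ensemble_msd(tracks, frame_interval = config$frame_interval)
  fit <- fit_msd(msd, n_points = p$n_points %||% 5,
                 exposure_time = config$exposure_time)
  jd <- tryCatch(
    jump_distance_fit(tracks, frame_interval = config$frame_interval,
                      n_components = p$n_components %||% 2),
    slb_insufficient_data_error = function(e) NULL)
  row <- tidy_to_row(tidy(fit))
  if (!is.null(jd)) {
    jtd <- tidy(jd)
    for (i in seq_len(nrow(jtd))) {
      row[[paste0("jd_d", i)]] <- jtd$d_coef[i]
      row[[paste0("jd_f", i)]] <- jtd$fraction[i]
    }
  }
  row
}

stage_frap <- function(config, inputs) {
  p <- config$frap
  trace <- inputs$trace
  if (!inherits(trace, "frap_trace")) {
    trace <- normalize_frap(trace,
                            prebleach_frames = p$prebleach_frames %||% 10)
  }
  fit <- fit_axelrod(trace, beam_radius = p$beam_radius %||% 1)
  tidy_to_row(tidy(fit))
}

stage_calcium <- function(config, inputs) {
  p <- config$calcium
  traces <- inputs$traces %||% extract_traces(
    inputs$stack, min_cell_area = p$min_cell_area %||% 20,
    frame_interval = config$frame_interval)
  peaks <- detect_peaks(traces,
                        min_height_multiple = p$min_height %||% 1.5,
                        min_prominence_multiple = p$min_prominence %||% 0.5)
  summarize_population(summarize_cells(traces, peaks))
}

stage_exclusion <- function(config, inputs) {
  p <- config$exclusion
  prep <- function(x) {
    img <- average_stack(x)
    rolling_ball_background(img, radius = p$radius %||% 50)
  }
  res <- compute_exclusion(prep(inputs$channel_contact),
                           prep(inputs$channel_probe))
  tibble(exclusion = res$exclusion, mean_in = res$mean_in,
         mean_out = res$mean_out, n_in = res$n_in, n_out = res$n_out)
}

stage_afm <- function(config, inputs) {
  p <- config$afm
  curve <- inputs$curve
  fit <- fit_hertz(curve, radius_um = p$radius_um %||% 18.5,
                   poisson_ratio = p$poisson %||% 0.5)
  events <- detect_push_through(curve,
                                gradient_window = p$window %||% 7,
                                drop_threshold = p$drop_threshold %||% 5)
  tibble(young_modulus_pa = fit$young_modulus,
         contact_point_um = fit$contact_point,
         n_push_through = nrow(events),
         z_jump_nm = if (nrow(events)) events$z_jump_nm[1] else NA_real_,
         slope_ratio = if (nrow(events)) events$slope_ratio[1] else NA_real_)
}

tidy_to_row <- function(td) {
  if ("term" %in% names(td)) {
    as_tibble(setNames(as.list(td$estimate), td$term))
  } else {
    td
  }
}
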