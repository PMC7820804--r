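#' Jump-distance (JD) mixture fit of single-step displacements
#'
#' Fits the distribution of squared single-frame displacements r^2 to a
#' mixture of freely diffusing populations,
#' \deqn{P(r^2, \Delta t) = \sum_j \frac{f_j}{4 D_j \Delta t}
#'   e^{-r^2 / (4 D_j \Delta t)},}
#' i.e. a mixture of exponentials in r^2 with means \eqn{4 D_j \Delta t}.
#' The default objective is the likelihood of the raw r^2 sample, maximized by
#' expectation-maximization (closed-form M-step, monotone in likelihood);
#' `method = "histogram"` instead least-squares fits the binned density as a
#' cross-check. If two components converge to indistinguishable coefficients
#' (ratio < 1.25) the fit collapses to one component and is flagged.
#'
#' @param tracks Tibble with `particle_id`, `frame`, `x`, `y` (um); apply
#'   [filter_tracks()] first. Only displacements between consecutive frames
#'   are used.
#' @param frame_interval s between frames (or a `frame_interval` attribute on
#'   `tracks`).
#' @param n_components Number of diffusing populations (default 2).
#' @param method `"mle"` (EM on raw r^2, default) or `"histogram"`.
#' @param min_steps Minimum number of single-step displacements required
#'   (default 30).
#' @param n_bins Histogram bins for `method = "histogram"`.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   falls below `tol` or after `max_iter` iterations.
#' @return A `jd_fit` object: `components` tibble (`fraction`, `d_coef`),
#'   sorted fast-first; `delta_t`; `n_steps`; `loglik`; `flags`.
#' @export
jump_distance_fit <- function(tracks, frame_interval = NULL, n_components = 2,
                              method = c("mle", "histogram"), min_steps = 30,
                              n_bins = 50, max_iter = 2000, tol = 1e-10) {
  method <- match.arg(method)
  frame_interval <- frame_interval %||%
    attr(tracks, "frame_interval", exact = TRUE)
  if (is.null(frame_interval)) {
    abort("`frame_interval` is required.", class = "slb_parameter_error")
  }
  r2 <- single_step_sq_displacements(tracks)
  if (length(r2) < min_steps) {
    abort(sprintf("Only %d single-step displacements (< %d required).",
                  length(r2), min_steps),
          class = "slb_insufficient_data_error")
  }
  r2 <- r2[r2 > 0]
  fit <- if (method == "mle") {
    em_exp_mixture(r2, n_components, max_iter, tol)
  } else {
    histogram_exp_mixture(r2, n_components, n_bins)
  }
  flags <- fit$flags
  means <- fit$means; fractions <- fit$fractions
  # degenerate multi-component fits collapse to one component: either the
  # coefficients are indistinguishable (ratio < 1.25) or the extra components
  # are not supported by the likelihood (BIC, mle method only)
  if (length(means) > 1) {
    o <- order(means, decreasing = TRUE)
    means <- means[o]; fractions <- fractions[o]
    ratios <- means[-length(means)] / means[-1]
    degenerate <- any(ratios < 1.25)
    if (!degenerate && method == "mle") {
      fit1 <- em_exp_mixture(r2, 1, max_iter, tol)
      n <- length(r2)
      bic_k <- -2 * fit$loglik + (2 * length(means) - 1) * log(n)
      bic_1 <- -2 * fit1$loglik + log(n)
      if (bic_1 <= bic_k) degenerate <- TRUE
    }
    if (degenerate) {
      flags <- c(flags, "components_collapsed")
      refit <- if (method == "mle") {
        em_exp_mixture(r2, 1, max_iter, tol)
      } else {
        histogram_exp_mixture(r2, 1, n_bins)
      }
      means <- refit$means; fractions <- refit$fractions
    }
  }
  o <- order(means, decreasing = TRUE)
  structure(
    list(components = tibble(fraction = fractions[o],
                             d_coef = means[o] / (4 * frame_interval)),
         delta_t = frame_interval, n_steps = length(r2),
         n_tracks = length(unique(tracks$particle_id)),
         method = method, loglik = fit$loglik, flags = flags),
    class = "jd_fit"
  )
}

single_step_sq_displacements <- function(tracks) {
  tl <- split(tracks[c("frame", "x", "y")], tracks$particle_id)
  unlist(lapply(tl, function(tr) {
    if (nrow(tr) < 2) return(numeric())
    keep <- diff(tr$frame) == 1L
    (diff(tr$x)^2 + diff(tr$y)^2)[keep]
  }), use.names = FALSE)
}

# EM for a mixture of exponential densities on x > 0; returns means (4 D dt)
em_exp_mixture <- function(x, k, max_iter = 2000, tol = 1e-10) {
  n <- length(x)
  if (k == 1) {
    m <- mean(x)
    return(list(means = m, fractions = 1,
                loglik = sum(-log(m) - x / m), flags = character()))
  }
  # deterministic quantile-spread initialization
  qs <- quantile(x, probs = seq(0.15, 0.85, length.out = k))
  means <- sort(unname(qs), decreasing = TRUE)
  means <- pmax(means, 1e-12)
  fractions <- rep(1 / k, k)
  ll_old <- -Inf
  flags <- character()
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) fractions[j] / means[j] * exp(-x / means[j]),
                   numeric(n))
    tot <- rowSums(dens)
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    fractions <- nk / n
    means <- pmax(colSums(resp * x) / nk, 1e-12)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  if (it == max_iter) flags <- c(flags, "max_iter_reached")
  list(means = means, fractions = fractions, loglik = ll, flags = flags)
}

# least squares on the binned empirical density of r^2
histogram_exp_mixture <- function(x, k, n_bins) {
  breaks <- seq(0, max(x) * (1 + 1e-9), length.out = n_bins + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  mids <- h$mids; dens <- h$density
  init <- em_exp_mixture(x, k, max_iter = 50)
  if (k == 1) {
    fit <- tryCatch(
      minpack.lm::nlsLM(dens ~ exp(-mids / m) / m,
                        start = list(m = init$means),
                        lower = 1e-12,
                        control = nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
    m <- if (is.null(fit)) init$means else unname(coef(fit)["m"])
    return(list(means = m, fractions = 1, loglik = NA_real_,
                flags = if (is.null(fit)) "histogram_fit_failed" else
                  character()))
  }
  if (k != 2) {
    abort("`method = \"histogram\"` supports 1 or 2 components.",
          class = "slb_parameter_error")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dens ~ f1 * exp(-mids / m1) / m1 + (1 - f1) * exp(-mids / m2) / m2,
      start = list(f1 = init$fractions[1], m1 = init$means[1],
                   m2 = init$means[2]),
      lower = c(f1 = 0, m1 = 1e-12, m2 = 1e-12),
      upper = c(f1 = 1, m1 = Inf, m2 = Inf),
      control = nls.control(maxiter = 500, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(means = init$means, fractions = init$fractions,
                loglik = init$loglik, flags = "histogram_fit_failed"))
  }
  p <- coef(fit)
  list(means = c(unname(p["m1"]), unname(p["m2"])),
       fractions = c(unname(p["f1"]), 1 - unname(p["f1"])),
       loglik = NA_real_, flags = character())
}

#' @export
print.jd_fit <- function(x, ...) {
  cat(sprintf("Jump-distance fit (%s, %d steps, dt = %g s):\n",
              x$method, x$n_steps, x$delta_t))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  D%d = %.4g um^2/s (f = %.3f)\n", i,
                x$components$d_coef[i], x$components$fraction[i]))
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
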