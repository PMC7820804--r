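# input checking helpers shared across modules

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "slb_parameter_error")
  }
  ok_lower <- if (allow_equal_lower) x >= lower else x > lower
  if (!ok_lower || x > upper) {
    abort(sprintf("`%s` = %g is outside the allowed range.", name, x),
          class = "slb_parameter_error")
  }
  invisible(x)
}

check_fractions <- function(f, name = "fractions", tol = 1e-8) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0)) {
    abort(sprintf("`%s` must be non-negative numbers.", name),
          class = "slb_parameter_error")
  }
  if (abs(sum(f) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %g).", name, sum(f)),
          class = "slb_parameter_error")
  }
  invisible(f)
}

check_matrix <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", name),
          class = "slb_input_error")
  }
  invisible(x)
}

# seeds: every stochastic function takes a `seed`; NULL leaves the RNG alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Retrieve the ground truth attached to a synthetic dataset
#'
#' Synthetic generators attach the parameters and per-unit labels they used as
#' a `ground_truth` attribute; this accessor retrieves it before any
#' attribute-stripping data manipulation.
#'
#' @param x An object produced by one of the `simulate_*()` generators.
#' @return The ground-truth object (a list or tibble), or `NULL` if absent.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)
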