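# shared I/O: TIFF stacks, delimited tables with schema validation, force
# curves, and result tables that embed their full parameter set.

#' Read a single-channel TIFF stack
#'
#' @param path Path to a single- or multi-page TIFF (8/16-bit or float).
#' @return Numeric array `[y, x, frame]`, frames in file order, pixel (0,0) at
#'   the top left. Intensities are returned as stored (integer TIFFs are not
#'   rescaled to `[0, 1]`).
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "slb_io_error")
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) {
                      abort(sprintf("Not a readable TIFF: %s (%s)", path,
                                    conditionMessage(e)),
                            class = "slb_io_error")
                    })
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1)))) {
    abort("Multi-sample (RGB) TIFF: single-channel required; split channels first.",
          class = "slb_io_error")
  }
  # undo the [0, 1] normalization applied to integer sample formats so raw
  # counts are returned; 32-bit float pages are already unscaled
  pages <- lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample", exact = TRUE) %||% 32L
    if (bits %in% c(8L, 16L)) p * (2^bits - 1) else p
  })
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All TIFF pages must have the same dimensions.",
          class = "slb_io_error")
  }
  array(unlist(pages), dim = c(dims[1, 1], dims[2, 1], length(pages)))
}

#' Write an image stack as multi-page TIFF
#'
#' Values are stored as 16-bit unsigned integers (the camera-native format for
#' the imaging data handled here): they are rounded and clamped to
#' `[0, 65535]`, so the write/read roundtrip is lossless for integer-valued
#' stacks such as photon counts.
#'
#' @param stack Numeric array `[y, x, frame]` or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  if (any(stack < 0) || any(stack > 65535)) {
    warn("Intensities clamped to [0, 65535] for 16-bit storage.")
  }
  pages <- lapply(seq_len(dim(stack)[3]), function(k) {
    pmin(pmax(round(stack[, , k]), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  reduce = FALSE, compression = "none")
  invisible(path)
}

#' Read a delimited table against a schema
#'
#' Delimiter (comma or tab) is auto-detected from the header line. The schema
#' names required columns and their types; extra columns are kept.
#'
#' @param path Path to a text table with a header row. Lines starting with `#`
#'   are treated as comments.
#' @param schema Named character vector, e.g.
#'   `c(z_um = "numeric", force_nn = "numeric")`.
#' @return Tibble with validated columns, row order preserved.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "slb_io_error")
  }
  lines <- readLines(path, n = 50L)
  header <- lines[!startsWith(lines, "#")][1]
  if (is.na(header)) {
    abort("No header row found.", class = "slb_schema_error")
  }
  delim <- if (grepl("\t", header)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(names(schema), names(tab))
  if (length(missing)) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "slb_schema_error")
  }
  for (col in names(schema)) {
    if (schema[[col]] == "numeric" && !is.numeric(tab[[col]])) {
      coerced <- suppressWarnings(as.numeric(as.character(tab[[col]])))
      bad <- which(is.na(coerced) & !is.na(tab[[col]]))
      if (length(bad)) {
        abort(sprintf("Column `%s` must be numeric (first bad row: %d).",
                      col, bad[1]),
              class = "slb_schema_error")
      }
      tab[[col]] <- coerced             # e.g. header-only files read as chr
    }
  }
  as_tibble(tab)
}

#' Read an AFM force curve from a two-column table
#'
#' @param path Path to a delimited table with columns `z_um` and `force_nn`
#'   (comment lines starting with `#` allowed).
#' @return A force-curve tibble usable by [fit_hertz()] and
#'   [detect_push_through()].
#' @export
read_force_curve <- function(path) {
  tab <- read_table(path, schema = c(z_um = "numeric", force_nn = "numeric"))
  check_force_curve(tab)
  tab
}

#' Write a result table with an embedded parameter header
#'
#' The full resolved parameter set (including seed and package version) is
#' written as `# key: value` comment lines followed by a tab-separated table,
#' so any output can be reproduced from the file alone.
#'
#' @param tbl Data frame of results.
#' @param path Output path.
#' @param params Named list of parameters to embed.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tbl, path, params = list()) {
  params$package_version <- as.character(packageVersion("slbtools"))
  hdr <- vapply(names(params), function(k) {
    sprintf("# %s: %s", k, paste(format(params[[k]]), collapse = " "))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tbl, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the parameter header of a result table
#'
#' @param path Path written by [write_result_table()].
#' @return Named list of parameter strings.
#' @export
read_result_params <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr))
  out <- lapply(kv, function(m) m[3])
  names(out) <- vapply(kv, function(m) m[2], character(1))
  out
}
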