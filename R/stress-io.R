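#' Read a per-slab local-stress table
#'
#' Parses whitespace-delimited local-stress output (the dialect family
#' produced by local-stress post-processing of coarse-grained bilayer
#' trajectories). Lines starting with `#` or `@` are comments. Three
#' dialects are supported:
#'
#' * `"lateral-2col"`: `z  s` — slab coordinate plus a precomputed lateral
#'   stress.
#' * `"tensor-diag"`: `z  sxx  syy  szz` — slab coordinate plus the three
#'   diagonal stress-tensor components (extra columns are ignored).
#' * `"tensor-9col"`: `z` plus the full tensor in row-major order
#'   (`xx xy xz yx yy yz zx zy zz`); the diagonal is taken from columns
#'   2, 6 and 10.
#'
#' Units are bar for stresses and nm for coordinates.
#'
#' @param source Path to a file, or a character vector of lines (length > 1,
#'   or containing newlines).
#' @param dialect One of `"lateral-2col"`, `"tensor-diag"`, `"tensor-9col"`.
#' @return A `raw_stress_table` tibble with column `z` plus either `s_lat`
#'   (lateral-2col) or `sxx`, `syy`, `szz` (tensor dialects).
#' @examples
#' lines <- vapply(1:8, function(i) sprintf("%.1f 3.0 3.0 1.0", i / 10), "")
#' read_stress_table(c("# comment", lines), dialect = "tensor-diag")
#' @export
read_stress_table <- function(source, dialect = c("lateral-2col", "tensor-diag",
                                                  "tensor-9col")) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) abort(
                        sprintf("Unknown stress-table dialect %s.",
                                deparse(dialect[1])),
                        class = "memcurv_error_config"))
  if (is.character(source) && (length(source) > 1L || grepl("\n", source[1]))) {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
  } else {
    lines <- readLines(source, warn = FALSE)
  }
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*($|[#@])", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) < 8) {
    abort(sprintf("Need at least 8 data rows, found %d.", length(lines)),
          class = "memcurv_error_insufficient_data")
  }
  tokens <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(tokens)
  min_cols <- switch(dialect, "lateral-2col" = 2L, "tensor-diag" = 4L,
                     "tensor-9col" = 10L)
  bad <- which(ncols < min_cols)
  if (length(bad)) {
    abort(sprintf("Line %d has %d columns; dialect '%s' needs at least %d.",
                  lineno[bad[1]], ncols[bad[1]], dialect, min_cols),
          class = "memcurv_error_parse")
  }
  vals <- suppressWarnings(lapply(tokens, as.numeric))
  bad <- which(vapply(vals, function(v) anyNA(v) || any(!is.finite(v)), TRUE))
  if (length(bad)) {
    abort(sprintf("Line %d contains a non-numeric or non-finite token.",
                  lineno[bad[1]]),
          class = "memcurv_error_parse")
  }
  col <- function(j) vapply(vals, `[[`, double(1), j)
  out <- switch(dialect,
    "lateral-2col" = tibble(z = col(1), s_lat = col(2)),
    "tensor-diag"  = tibble(z = col(1), sxx = col(2), syy = col(3), szz = col(4)),
    "tensor-9col"  = tibble(z = col(1), sxx = col(2), syy = col(6), szz = col(10))
  )
  class(out) <- c("raw_stress_table", class(out))
  attr(out, "dialect") <- dialect
  out
}

#' Lateral stress profile from a raw stress table
#'
#' Computes \eqn{s(z) = (\sigma_{xx}(z) + \sigma_{yy}(z))/2 - \sigma_{zz}(z)}
#' for tensor dialects, or passes the precomputed lateral column through.
#' Orientation and centering are left as "unknown" until set explicitly with
#' [center_profile()] and [set_orientation()].
#'
#' @param table A `raw_stress_table` from [read_stress_table()], or any data
#'   frame with column `z` plus either `s_lat` or `sxx`/`syy`/`szz`.
#' @param n_frames Number of trajectory frames behind the table (metadata).
#' @return A [stress_profile()].
#' @export
lateral_stress <- function(table, n_frames = 1L) {
  if (!is.data.frame(table) || !"z" %in% names(table)) {
    abort("`table` must be a data frame with a `z` column.",
          class = "memcurv_error_format")
  }
  if ("s_lat" %in% names(table)) {
    s <- table$s_lat
  } else if (all(c("sxx", "syy", "szz") %in% names(table))) {
    s <- (table$sxx + table$syy) / 2 - table$szz
  } else {
    abort("`table` must contain `s_lat` or the diagonal components `sxx`, `syy`, `szz`.",
          class = "memcurv_error_format")
  }
  stress_profile(table$z, s, orientation = "unknown", centered = NA,
                 n_frames = n_frames)
}

#' Center a stress profile on the bilayer midplane
#'
#' Shifts the z grid so the midplane maps to z = 0. By default the midplane
#' is the geometric center of the box (midpoint of the z range); membrane
#' drift correction, if needed, is upstream of this package.
#'
#' @param p A [stress_profile()].
#' @param midplane Optional midplane coordinate in the current grid; must lie
#'   inside the z range. Default: the geometric box center.
#' @return The centered profile (`centered = TRUE`); grid spacing unchanged.
#' @examples
#' p <- stress_profile(seq(0, 10, by = 0.5), rnorm(21))
#' range(center_profile(p)$z) # about [-5, 5]
#' @export
center_profile <- function(p, midplane = NULL) {
  assert_profile(p)
  zr <- range(p$z)
  if (is.null(midplane)) {
    midplane <- mean(zr)
  } else if (midplane < zr[1] || midplane > zr[2]) {
    abort(sprintf("midplane %.4g lies outside the grid [%.4g, %.4g].",
                  midplane, zr[1], zr[2]),
          class = "memcurv_error_domain")
  }
  new_stress_profile(p$z - midplane, p$s,
                     orientation = attr(p, "orientation"), centered = TRUE,
                     n_frames = attr(p, "n_frames"), spacing = attr(p, "spacing"))
}

#' Set the leaflet orientation of a stress profile
#'
#' The canonical convention has the upper leaflet and the exterior solution
#' at positive z, with the membrane normal pointing from the upper leaflet
#' into the exterior. If the profile was recorded with the exterior at
#' negative z, the grid is reflected (z to -z, data reversed) so the
#' canonical convention holds afterwards.
#'
#' @param p A centered [stress_profile()].
#' @param exterior_at_positive_z `TRUE` if, in the profile's current frame,
#'   the exterior solution lies at positive z.
#' @return The profile in canonical orientation
#'   (`orientation = "exterior-positive"`).
#' @export
set_orientation <- function(p, exterior_at_positive_z = TRUE) {
  assert_profile(p)
  if (!isTRUE(attr(p, "centered"))) {
    abort("Center the profile (see `center_profile()`) before setting orientation.",
          class = "memcurv_error_state")
  }
  out <- if (exterior_at_positive_z) p else reflect_profile(p)
  attr(out, "orientation") <- "exterior-positive"
  out
}

#' @rdname set_orientation
#' @details `reflect_profile()` is the bare involution z to -z (data
#'   reversed) with the orientation flag toggled; applying it twice returns
#'   the original profile.
#' @export
reflect_profile <- function(p) {
  assert_profile(p)
  flipped <- switch(attr(p, "orientation"),
                    "exterior-positive" = "exterior-negative",
                    "exterior-negative" = "exterior-positive",
                    "unknown")
  new_stress_profile(rev(-p$z), rev(p$s),
                     orientation = flipped, centered = attr(p, "centered"),
                     n_frames = attr(p, "n_frames"), spacing = attr(p, "spacing"))
}

#' Residual membrane tension of a stress profile
#'
#' Trapezoidal integral \eqn{\int s(z)\,dz} in bar nm. A tension-free
#' bilayer (the usual NPT setup at 1 bar with semi-isotropic coupling)
#' should give a value near zero; finite sampling leaves a residual, so
#' values beyond `tolerance` raise a warning rather than an error.
#'
#' @param p A centered [stress_profile()].
#' @param tolerance Absolute tolerance in bar nm beyond which the profile is
#'   flagged (default 1.0).
#' @return The tension (bar nm) with attribute `flagged` (logical).
#' @export
tension <- function(p, tolerance = 1.0) {
  assert_profile(p)
  tens <- trapz(p$z, p$s)
  flagged <- abs(tens) > tolerance
  if (flagged) {
    warn(sprintf("Residual tension %.4g bar nm exceeds tolerance %.4g: the bilayer may not be tension-free.",
                 tens, tolerance),
         class = "memcurv_warning_tension")
  }
  structure(tens, flagged = flagged)
}

#' Write a stress profile in a readable dialect
#'
#' Writes `p` in one of the dialects [read_stress_table()] accepts, so that
#' write-then-read round-trips. Tensor dialects reconstruct a diagonal with
#' `sxx = syy = s` and `szz = 0`, which inverts exactly under
#' [lateral_stress()]. Metadata are written as `# key = value` comment
#' lines.
#'
#' @param p A [stress_profile()].
#' @param path Output file path.
#' @param dialect One of `"lateral-2col"`, `"tensor-diag"`, `"tensor-9col"`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path, dialect = c("lateral-2col", "tensor-diag",
                                               "tensor-9col")) {
  assert_profile(p)
  dialect <- match.arg(dialect)
  meta <- c(
    sprintf("# dialect = %s", dialect),
    sprintf("# orientation = %s", attr(p, "orientation")),
    sprintf("# centered = %s", format(attr(p, "centered"))),
    sprintf("# n_frames = %d", attr(p, "n_frames")),
    sprintf("# box_height_nm = %.17g", attr(p, "box_height"))
  )
  fmt <- function(...) sprintf(paste(rep("%.17g", ...length()), collapse = " "), ...)
  rows <- switch(dialect,
    "lateral-2col" = mapply(fmt, p$z, p$s),
    "tensor-diag"  = mapply(fmt, p$z, p$s, p$s, rep(0, nrow(p))),
    "tensor-9col"  = mapply(function(z, s) fmt(z, s, 0, 0, 0, s, 0, 0, 0, 0),
                            p$z, p$s)
  )
  writeLines(c(meta, rows), path)
  invisible(path)
}

#' @rdname write_profile
#' @details `write_stress_csv()` writes the canonical comma-separated form
#'   (columns `z_nm`, `s_bar`) with the same metadata comment header.
#' @export
write_stress_csv <- function(p, path) {
  assert_profile(p)
  meta <- c(
    sprintf("# orientation = %s", attr(p, "orientation")),
    sprintf("# centered = %s", format(attr(p, "centered"))),
    sprintf("# n_frames = %d", attr(p, "n_frames"))
  )
  writeLines(c(meta, "z_nm,s_bar",
               sprintf("%.17g,%.17g", p$z, p$s)), path)
  invisible(path)
}

#' Read a sequence of per-block stress tables as profiles
#'
#' Convenience wrapper for multi-file output (one local-stress table per
#' trajectory block): each file is read, converted to a lateral stress
#' profile, centered, and put in canonical orientation, ready for
#' [moment_timeseries()].
#'
#' @param paths Character vector of file paths, in block order.
#' @inheritParams read_stress_table
#' @inheritParams set_orientation
#' @param midplane Optional midplane passed to [center_profile()].
#' @return A list of [stress_profile()]s.
#' @export
read_profile_blocks <- function(paths, dialect = "lateral-2col",
                                exterior_at_positive_z = TRUE, midplane = NULL) {
  purrr::map(paths, function(path) {
    read_stress_table(path, dialect = dialect) |>
      lateral_stress() |>
      center_profile(midplane = midplane) |>
      set_orientation(exterior_at_positive_z = exterior_at_positive_z)
  })
}
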