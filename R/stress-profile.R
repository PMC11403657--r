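#' Construct a lateral stress profile
#'
#' A `stress_profile` is a tibble with columns `z` (slab coordinate, nm,
#' uniform spacing, strictly increasing) and `s` (lateral stress, bar),
#' carrying metadata on orientation (does positive z point toward the
#' exterior solution?), centering (is z = 0 the bilayer midplane?), the
#' number of trajectory frames averaged, and the box height. The lateral
#' stress is \eqn{s(z) = (\sigma_{xx} + \sigma_{yy})/2 - \sigma_{zz}}.
#'
#' The grid is interpreted as slab (bin) centers, so the box height equals
#' the number of slabs times the spacing. Non-uniform grids are rejected
#' rather than resampled, to avoid silent interpolation error.
#'
#' @param z Numeric vector of slab coordinates (nm), uniformly spaced and
#'   strictly increasing, length >= 8.
#' @param s Numeric vector of lateral stresses (bar), same length as `z`,
#'   all finite.
#' @param orientation One of `"unknown"`, `"exterior-positive"`,
#'   `"exterior-negative"`: where the exterior solution lies along z.
#' @param centered `TRUE` if z = 0 is the bilayer midplane, `FALSE` if not,
#'   `NA` if unknown.
#' @param n_frames Number of trajectory frames averaged into `s` (>= 1).
#' @return A `stress_profile` tibble.
#' @seealso [lateral_stress()], [center_profile()], [set_orientation()]
#' @examples
#' p <- stress_profile(z = seq(-5, 5, by = 0.5), s = rep(0, 21))
#' attr(p, "box_height")
#' @export
stress_profile <- function(z, s,
                           orientation = c("unknown", "exterior-positive",
                                           "exterior-negative"),
                           centered = NA, n_frames = 1L) {
  orientation <- match.arg(orientation)
  z <- as.double(z)
  s <- as.double(s)
  if (length(z) != length(s)) {
    abort("`z` and `s` must have the same length.", class = "memcurv_error_format")
  }
  if (length(z) < 8) {
    abort("A stress profile needs at least 8 slabs.",
          class = "memcurv_error_insufficient_data")
  }
  if (anyNA(z) || any(!is.finite(z))) {
    abort("Slab coordinates must be finite.", class = "memcurv_error_format")
  }
  if (anyNA(s) || any(!is.finite(s))) {
    abort("Lateral stress values must be finite.", class = "memcurv_error_format")
  }
  dz <- diff(z)
  if (any(dz <= 0)) {
    abort("Slab coordinates must be strictly increasing.",
          class = "memcurv_error_format")
  }
  spacing <- mean(dz)
  if (max(abs(dz - spacing)) > 1e-6 * spacing) {
    abort("Slab grid must be uniform to within 1 part in 1e6 (non-uniform grids are rejected, not resampled).",
          class = "memcurv_error_format")
  }
  new_stress_profile(z, s, orientation = orientation, centered = centered,
                     n_frames = as.integer(n_frames), spacing = spacing)
}

## Fast path used by generators that construct valid grids by design.
new_stress_profile <- function(z, s, orientation, centered, n_frames, spacing) {
  new_tibble(
    list(z = z, s = s),
    nrow = length(z),
    class = "stress_profile",
    orientation = orientation,
    centered = centered,
    n_frames = n_frames,
    spacing = spacing,
    box_height = length(z) * spacing
  )
}

is_stress_profile <- function(x) inherits(x, "stress_profile")

assert_profile <- function(p, arg = "p") {
  if (!is_stress_profile(p)) {
    abort(sprintf("`%s` must be a stress_profile (see `stress_profile()`).", arg),
          class = "memcurv_error_type")
  }
  invisible(p)
}

#' @export
print.stress_profile <- function(x, ...) {
  cat(sprintf(
    "<stress_profile: %d slabs, spacing %.4g nm, box %.4g nm, %d frame%s>\n",
    nrow(x), attr(x, "spacing"), attr(x, "box_height"),
    attr(x, "n_frames"), if (attr(x, "n_frames") == 1L) "" else "s"
  ))
  cat(sprintf("  orientation: %s; centered: %s\n",
              attr(x, "orientation"), format(attr(x, "centered"))))
  NextMethod()
}

#' @rdname autoplot.division_prediction
#' @export
autoplot.stress_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$z, y = .data$s)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = "lateral stress s(z) (bar)")
}
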