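#' Spontaneous curvature parameter from the stress-profile first moment
#'
#' For an asymmetric bilayer the product of bending rigidity and spontaneous
#' curvature follows from the first moment of the lateral stress profile:
#' \deqn{2\kappa m = -\int z\, s(z)\, dz}
#' evaluated by the trapezoidal rule over the native grid (no
#' interpolation), with z = 0 at the bilayer midplane and the exterior
#' solution at positive z. The sign convention makes a membrane that bulges
#' toward the exterior compartment carry positive spontaneous curvature;
#' `moment_sign = +1` selects the opposite convention should your upstream
#' stress tool define s(z) with the other sign.
#'
#' The integral, in bar nm^2, is converted to kBT/nm using the thermal
#' energy at `temperature` (see [bar_nm2_to_kbt_per_nm()]).
#'
#' @param p A [stress_profile()], centered and in canonical orientation
#'   (`exterior-positive`); see [center_profile()] and [set_orientation()].
#' @param temperature Temperature in kelvin for the kBT conversion.
#' @param moment_sign Either -1 (default, canonical convention) or +1.
#' @return The scalar 2-kappa-m in kBT/nm.
#' @examples
#' z <- seq(-8, 8, by = 0.01)
#' p <- stress_profile(z, z * exp(-z^2 / 2), centered = TRUE,
#'                     orientation = "exterior-positive")
#' spontaneous_curvature_moment(p) # -sqrt(2*pi) bar nm^2 in kBT/nm
#' @export
spontaneous_curvature_moment <- function(p, temperature = 303.15,
                                         moment_sign = -1) {
  assert_profile(p)
  if (!isTRUE(attr(p, "centered"))) {
    abort("Profile must be centered on the bilayer midplane first (`center_profile()`).",
          class = "memcurv_error_state")
  }
  if (!identical(attr(p, "orientation"), "exterior-positive")) {
    abort("Profile orientation must be canonical (exterior at positive z); use `set_orientation()`.",
          class = "memcurv_error_state")
  }
  if (!moment_sign %in% c(-1, 1)) {
    abort("`moment_sign` must be -1 or +1.", class = "memcurv_error_config")
  }
  moment_sign * trapz(p$z, p$z * p$s) * bar_nm2_to_kbt_per_nm(temperature)
}

#' Per-block time series of first moments
#'
#' Applies [spontaneous_curvature_moment()] to each profile of a sequence
#' (e.g. one profile per trajectory block), preserving order. All profiles
#' must share the same grid, centering and orientation; the resulting series
#' feeds [blocking_sem()].
#'
#' @param profiles List of [stress_profile()]s on a common grid.
#' @inheritParams spontaneous_curvature_moment
#' @return Numeric vector of 2-kappa-m values (kBT/nm), one per profile.
#' @export
moment_timeseries <- function(profiles, temperature = 303.15, moment_sign = -1) {
  if (!length(profiles)) {
    abort("`profiles` must contain at least one stress_profile.",
          class = "memcurv_error_insufficient_data")
  }
  purrr::walk(profiles, assert_profile, arg = "profiles[[i]]")
  z0 <- profiles[[1]]$z
  same <- purrr::map_lgl(profiles, function(p) {
    length(p$z) == length(z0) && max(abs(p$z - z0)) <= 1e-9
  })
  if (!all(same)) {
    abort("All profiles must share the same z grid.",
          class = "memcurv_error_domain")
  }
  purrr::map_dbl(profiles, spontaneous_curvature_moment,
                 temperature = temperature, moment_sign = moment_sign)
}

#' Blocking-analysis standard error of the mean
#'
#' Flyvbjerg-Petersen blocking for autocorrelated series: neighbouring
#' pairs are repeatedly averaged, and at each blocking level k the SEM is
#' estimated as \eqn{s_k = \sqrt{c_k/(n_k - 1)}} with \eqn{c_k} the
#' population variance and \eqn{n_k} the number of blocks. For correlated
#' data the estimate grows with k until blocks are effectively independent,
#' then plateaus. The reported SEM is the estimate at the first plateau —
#' the first level whose estimate lies within its own one-sigma uncertainty
#' (\eqn{s_k/\sqrt{2(n_k-1)}}) of the next level's. If no plateau occurs
#' before blocks run out, the maximum estimate across levels is returned
#' with `plateau_found = FALSE` (a lower bound on the true SEM).
#'
#' @param series Numeric vector, length >= 16 (e.g. per-block first
#'   moments from [moment_timeseries()]).
#' @param min_blocks Stop blocking when fewer blocks than this remain
#'   (default 4; variance estimates from fewer blocks are too noisy to
#'   compare).
#' @return A one-row tibble with columns `sem`, `plateau_found`,
#'   `plateau_level` (0-based; `NA` if none) and `n_levels`.
#' @examples
#' x <- rnorm(4096)
#' blocking_sem(x)$sem # close to 1/64
#' @export
blocking_sem <- function(series, min_blocks = 4L) {
  series <- as.double(series)
  if (anyNA(series)) {
    abort("`series` must not contain missing values.",
          class = "memcurv_error_format")
  }
  if (length(series) < 16L) {
    abort(sprintf("Blocking analysis needs at least 16 points, got %d.",
                  length(series)),
          class = "memcurv_error_insufficient_data")
  }
  sems <- double()
  errs <- double()
  x <- series
  while (length(x) >= min_blocks) {
    nk <- length(x)
    ck <- mean((x - mean(x))^2)          # population variance of the blocks
    sk <- sqrt(ck / (nk - 1))
    sems <- c(sems, sk)
    errs <- c(errs, sk / sqrt(2 * (nk - 1)))
    x <- (x[seq(1L, nk - nk %% 2L, by = 2L)] + x[seq(2L, nk, by = 2L)]) / 2
  }
  n_levels <- length(sems)
  plateau <- NA_integer_
  for (k in seq_len(n_levels - 1L)) {
    if (abs(sems[k + 1L] - sems[k]) <= errs[k]) {
      plateau <- k
      break
    }
  }
  if (is.na(plateau)) {
    tibble(sem = max(sems), plateau_found = FALSE,
           plateau_level = NA_integer_, n_levels = n_levels)
  } else {
    tibble(sem = sems[plateau], plateau_found = TRUE,
           plateau_level = plateau - 1L, n_levels = n_levels)
  }
}

#' Peptide area fraction from the end-to-end distance
#'
#' The membrane area covered by a bound peptide is modelled as a disk whose
#' diameter is the peptide's mean end-to-end distance (the lipid:anchor
#' complex is free to rotate, so the covered area is circular):
#' \deqn{\phi = n_{pep}\,\pi (r_{ee} d_{factor}/2)^2 / A_{box}.}
#'
#' @param ree Mean end-to-end distance of the peptide (nm), >= 0.
#' @param n_peptides Number of bound peptides in the patch (default 1).
#' @param box_area Membrane patch area (nm^2), > 0.
#' @param disk_factor Ratio of disk diameter to `ree` (default 1: diameter
#'   equals the end-to-end distance — the minimal reading of a circular
#'   footprint sized by the peptide extent).
#' @return Area fraction phi in `[0, 1)`. A result >= 1 violates the
#'   dilute-regime assumption and raises an error.
#' @examples
#' area_fraction(ree = 2, n_peptides = 1, box_area = 10.4) # pi/10.4
#' @export
area_fraction <- function(ree, n_peptides = 1L, box_area, disk_factor = 1) {
  if (ree < 0) abort("`ree` must be non-negative.", class = "memcurv_error_domain")
  if (box_area <= 0) abort("`box_area` must be positive.", class = "memcurv_error_domain")
  if (n_peptides < 0) abort("`n_peptides` must be non-negative.", class = "memcurv_error_domain")
  phi <- n_peptides * pi * (ree * disk_factor / 2)^2 / box_area
  if (phi >= 1) {
    abort(sprintf("Area fraction %.3g >= 1: the dilute-regime assumption is violated.", phi),
          class = "memcurv_error_domain")
  }
  phi
}

#' Build a coverage-curvature point
#'
#' One measured (phi, 2-kappa-m, SEM) point for a given membrane
#' composition, as a one-row tibble; rows sharing a `label` form a
#' coverage-curvature series for [fit_through_origin()].
#'
#' @param two_kappa_m Spontaneous-curvature parameter 2-kappa-m (kBT/nm).
#' @param sem Standard error of the mean of `two_kappa_m` (kBT/nm, >= 0).
#' @param phi Peptide area fraction in `[0, 1)`.
#' @param label Membrane composition / peptide charge tag.
#' @return A one-row tibble with columns `label`, `phi`, `two_kappa_m`, `sem`.
#' @export
curvature_estimate <- function(two_kappa_m, sem = 0, phi, label = "") {
  if (!is.finite(two_kappa_m)) abort("`two_kappa_m` must be finite.",
                                     class = "memcurv_error_domain")
  if (sem < 0) abort("`sem` must be non-negative.", class = "memcurv_error_domain")
  if (phi < 0 || phi >= 1) abort("`phi` must lie in [0, 1).",
                                 class = "memcurv_error_domain")
  tibble(label = label, phi = phi, two_kappa_m = two_kappa_m, sem = sem)
}

check_coverage_series <- function(data) {
  need <- c("phi", "two_kappa_m")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    abort("`data` must be a data frame with columns `phi` and `two_kappa_m` (and optionally `sem`, `label`).",
          class = "memcurv_error_format")
  }
  if (!nrow(data)) {
    abort("Need at least one coverage-curvature point.",
          class = "memcurv_error_insufficient_data")
  }
  if (anyDuplicated(data$phi)) {
    abort("Area fractions `phi` must be distinct within a series.",
          class = "memcurv_error_format")
  }
  if ("label" %in% names(data) && length(unique(data$label)) > 1L) {
    abort("All points of a coverage-curvature series must share one label; fit compositions separately (e.g. with `dplyr::group_by()`).",
          class = "memcurv_error_format")
  }
  invisible(data)
}

#' Fit the coverage-curvature line through the origin
#'
#' The spontaneous curvature of a peptide-decorated membrane vanishes at
#' zero coverage, so 2-kappa-m versus the area fraction phi is fitted by
#' least squares with zero intercept. When all points carry positive SEMs
#' the fit is weighted by 1/sem^2:
#' \deqn{b = \sum w_i x_i y_i / \sum w_i x_i^2, \quad
#'       se(b) = (\sum w_i x_i^2)^{-1/2},}
#' otherwise the unweighted estimator is used with the residual-based
#' standard error. The slope, d(2-kappa-m)/d-phi, divided by twice the
#' bending rigidity gives the local curvature per unit coverage
#' \eqn{m_0 = b/(2\kappa)} and the local curvature radius \eqn{1/m_0}.
#'
#' @param data A coverage-curvature series: data frame with columns `phi`,
#'   `two_kappa_m` and optionally `sem` (kBT/nm) and `label` (single value).
#' @param kappa Bending rigidity kappa in kBT (default 25.2, the value used
#'   for the calibration membranes).
#' @return A `curvature_fit` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @examples
#' pts <- make_coverage_dataset(slope = 13.3, phis = c(0.03, 0.06),
#'                              sems = c(0.05, 0.05), seed = 1)
#' fit <- fit_through_origin(pts)
#' glance(fit)
#' @export
fit_through_origin <- function(data, kappa = 25.2) {
  check_coverage_series(data)
  if (kappa <= 0) abort("`kappa` must be positive.", class = "memcurv_error_domain")
  x <- data$phi
  y <- data$two_kappa_m
  sem <- if ("sem" %in% names(data)) data$sem else rep(0, length(x))
  if (all(x == 0)) {
    abort("All `phi` are zero: the through-origin slope is unidentified.",
          class = "memcurv_error_degenerate")
  }
  weighted <- all(sem > 0)
  if (!weighted && any(sem > 0)) {
    abort("Either all points must have sem > 0 (weighted fit) or none (unweighted).",
          class = "memcurv_error_format")
  }
  w <- if (weighted) 1 / sem^2 else rep(1, length(x))
  sxx <- sum(w * x^2)
  slope <- sum(w * x * y) / sxx
  if (weighted) {
    slope_err <- sqrt(1 / sxx)
  } else if (length(x) >= 2L) {
    s2 <- sum((y - slope * x)^2) / (length(x) - 1L)
    slope_err <- sqrt(s2 / sxx)
  } else {
    slope_err <- NA_real_
  }
  m0 <- slope / (2 * kappa)
  structure(
    list(slope = slope, slope_err = slope_err, kappa = kappa,
         m0 = m0, m0_inv = if (m0 != 0) 1 / m0 else NA_real_,
         weighted = weighted, n = length(x),
         label = if ("label" %in% names(data)) data$label[1] else "",
         data = as_tibble(data)),
    class = "curvature_fit"
  )
}

#' @export
print.curvature_fit <- function(x, ...) {
  cat(sprintf("<curvature_fit%s: %d point%s, %s>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$n, if (x$n == 1L) "" else "s",
              if (x$weighted) "weighted 1/sem^2" else "unweighted"))
  cat(sprintf("  slope d(2km)/dphi = %.4g +/- %.4g kBT/nm\n", x$slope, x$slope_err))
  cat(sprintf("  m0 = %.4g 1/nm (kappa = %.3g kBT); 1/m0 = %.4g nm\n",
              x$m0, x$kappa, x$m0_inv))
  invisible(x)
}

#' Tidy and summarise curvature fits
#'
#' @param x A `curvature_fit` from [fit_through_origin()].
#' @param ... Unused.
#' @return `tidy()`: one row per model term with `estimate` and `std.error`;
#'   `glance()`: a one-row tibble with `slope`, `slope_err`, `kappa`, `m0`,
#'   `m0_inv`, `n`, `weighted`.
#' @export
tidy.curvature_fit <- function(x, ...) {
  tibble(term = "phi", estimate = x$slope, std.error = x$slope_err)
}

#' @rdname tidy.curvature_fit
#' @export
glance.curvature_fit <- function(x, ...) {
  tibble(slope = x$slope, slope_err = x$slope_err, kappa = x$kappa,
         m0 = x$m0, m0_inv = x$m0_inv, n = x$n, weighted = x$weighted,
         label = x$label)
}

#' Flip curvature quantities to the opposite leaflet
#'
#' A species adsorbed to the inner rather than the outer leaflet generates
#' the mirror-image membrane asymmetry, so the measured curvature changes
#' sign while its uncertainty is unchanged. Works on coverage-curvature
#' tibbles (negates `two_kappa_m`) and on [fit_through_origin()] results
#' (negates `slope`, `m0`, `m0_inv`); labels are annotated
#' `"inner-leaflet"`. Applying the flip twice is the identity up to label
#' annotation.
#'
#' @param x A coverage-curvature data frame or a `curvature_fit`.
#' @param ... Unused.
#' @return An object of the same type with curvatures negated.
#' @export
leaflet_flip <- function(x, ...) UseMethod("leaflet_flip")

#' @export
leaflet_flip.data.frame <- function(x, ...) {
  if (!"two_kappa_m" %in% names(x)) {
    abort("`x` must have a `two_kappa_m` column.", class = "memcurv_error_format")
  }
  x$two_kappa_m <- -x$two_kappa_m
  if ("label" %in% names(x)) x$label <- annotate_flip(x$label)
  x
}

#' @export
leaflet_flip.curvature_fit <- function(x, ...) {
  x$slope <- -x$slope
  x$m0 <- -x$m0
  x$m0_inv <- if (!is.na(x$m0_inv)) -x$m0_inv else NA_real_
  x$label <- annotate_flip(x$label)
  x
}

annotate_flip <- function(label) {
  ifelse(endsWith(label, " [inner-leaflet]"),
         sub(" \\[inner-leaflet\\]$", "", label),
         paste0(label, " [inner-leaflet]"))
}
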