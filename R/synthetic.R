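#' Recipe for synthetic stress-profile ensembles
#'
#' Describes a tension-free bilayer-like lateral stress profile with a
#' planted first moment, plus per-frame white noise, used to test the
#' moment pipeline against known ground truth. The mean profile is the sum
#' of a symmetric part (two repulsive Gaussian peaks at the headgroup
#' positions, balanced by a central Gaussian trough so the zeroth moment
#' vanishes exactly on the grid) and an antisymmetric part
#' \eqn{g(z) = c\, z\, e^{-z^2/2w^2}} scaled so the discrete first moment
#' \eqn{\int z\,s(z)\,dz} equals `planted_first_moment` exactly.
#'
#' Defaults mimic the scale of coarse-grained bilayer stress profiles
#' (order-of-magnitude realism only): a 16 nm box, headgroup peaks at
#' +/- 2 nm, sub-nm widths, amplitudes of order 100 bar.
#'
#' @param box_height Box height in nm; `spacing` must divide it.
#' @param spacing Slab width in nm (grid points are slab centers).
#' @param headgroup_position Position +/- z_h of the repulsive peaks (nm).
#' @param peak_amplitude Amplitude of the headgroup peaks (bar).
#' @param trough_amplitude Nominal amplitude of the central trough (bar);
#'   rescaled to make the profile tension-free.
#' @param peak_width,trough_width Gaussian widths (nm); `trough_width` also
#'   sets the width of the antisymmetric component.
#' @param planted_first_moment Target discrete first moment
#'   \eqn{\int z\,s\,dz} in bar nm^2 (the moment pipeline then returns its
#'   negative, converted to kBT/nm).
#' @param noise_sd Per-slab, per-frame white-noise standard deviation (bar).
#' @param n_frames Number of frames to generate.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `profile_recipe` list.
#' @export
profile_recipe <- function(box_height = 16, spacing = 0.1,
                           headgroup_position = 2, peak_amplitude = 100,
                           trough_amplitude = 100, peak_width = 0.5,
                           trough_width = 1, planted_first_moment = 0,
                           noise_sd = 0, n_frames = 1L, seed = 1L) {
  n <- box_height / spacing
  if (abs(n - round(n)) > 1e-9 || round(n) < 8) {
    abort("`spacing` must divide `box_height` into at least 8 slabs.",
          class = "memcurv_error_config")
  }
  if (headgroup_position <= 0 || headgroup_position >= box_height / 2) {
    abort("`headgroup_position` must lie inside the half-box.",
          class = "memcurv_error_config")
  }
  if (peak_width <= 0 || trough_width <= 0 || noise_sd < 0 || n_frames < 1) {
    abort("Widths must be positive, `noise_sd` non-negative, `n_frames` >= 1.",
          class = "memcurv_error_config")
  }
  structure(list(box_height = box_height, spacing = spacing,
                 headgroup_position = headgroup_position,
                 peak_amplitude = peak_amplitude,
                 trough_amplitude = trough_amplitude,
                 peak_width = peak_width, trough_width = trough_width,
                 planted_first_moment = planted_first_moment,
                 noise_sd = noise_sd, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "profile_recipe")
}

#' Generate a stress-profile ensemble with planted ground truth
#'
#' Realises a [profile_recipe()]: the tension-free mean profile with the
#' planted first moment, plus `n_frames` noisy per-frame profiles
#' (mean + white Gaussian noise per slab). All profiles come centered and
#' in canonical orientation. The returned ground truth records the planted
#' moment, its equivalent 2-kappa-m in kBT/nm, and the analytic per-frame
#' moment noise so tests can calibrate recovery.
#'
#' @param r A [profile_recipe()].
#' @param temperature Temperature for the ground-truth kBT conversion.
#' @return A list with `profiles` (list of [stress_profile()]s, length
#'   `n_frames`), `mean_profile` (noise-free), and `truth` (list:
#'   `first_moment_bar_nm2`, `two_kappa_m_kbt_per_nm`,
#'   `moment_sd_per_frame`, `sem_expected`).
#' @examples
#' ens <- make_profile_ensemble(profile_recipe(planted_first_moment = -2.5))
#' spontaneous_curvature_moment(ens$mean_profile)
#' @export
make_profile_ensemble <- function(r, temperature = 303.15) {
  stopifnot(inherits(r, "profile_recipe"))
  n <- round(r$box_height / r$spacing)
  z <- (seq_len(n) - (n + 1) / 2) * r$spacing     # symmetric slab centers
  gauss <- function(z0, w) exp(-(z - z0)^2 / (2 * w^2))
  peaks <- gauss(r$headgroup_position, r$peak_width) +
    gauss(-r$headgroup_position, r$peak_width)
  trough <- gauss(0, r$trough_width)
  # balance the trough so the discrete zeroth moment vanishes exactly
  s_even <- r$peak_amplitude * peaks -
    (r$peak_amplitude * trapz(z, peaks) / trapz(z, trough)) * trough
  g_shape <- z * exp(-z^2 / (2 * r$trough_width^2))
  s_odd <- if (r$planted_first_moment != 0) {
    (r$planted_first_moment / trapz(z, z * g_shape)) * g_shape
  } else {
    rep(0, n)
  }
  s_mean <- s_even + s_odd
  mean_profile <- new_stress_profile(z, s_mean,
                                     orientation = "exterior-positive",
                                     centered = TRUE, n_frames = r$n_frames,
                                     spacing = r$spacing)
  profiles <- withr::with_seed(r$seed, {
    lapply(seq_len(r$n_frames), function(i) {
      s <- s_mean + if (r$noise_sd > 0) rnorm(n, sd = r$noise_sd) else 0
      new_stress_profile(z, s, orientation = "exterior-positive",
                         centered = TRUE, n_frames = 1L, spacing = r$spacing)
    })
  })
  # trapezoid weights give the analytic sd of the per-frame first moment
  wts <- c(r$spacing / 2, rep(r$spacing, n - 2), r$spacing / 2)
  conv <- bar_nm2_to_kbt_per_nm(temperature)
  moment_sd <- r$noise_sd * sqrt(sum((wts * z)^2)) * conv
  list(
    profiles = profiles,
    mean_profile = mean_profile,
    truth = list(
      first_moment_bar_nm2 = r$planted_first_moment,
      two_kappa_m_kbt_per_nm = -r$planted_first_moment * conv,
      moment_sd_per_frame = moment_sd,
      sem_expected = moment_sd / sqrt(r$n_frames)
    )
  )
}

#' Generate a stationary AR(1) series
#'
#' First-order autoregressive series with planted mean, marginal standard
#' deviation and lag-1 autocorrelation `rho`, started from the stationary
#' distribution — the standard test instrument for blocking-analysis
#' calibration (the true standard error of its mean is
#' \eqn{\sigma\sqrt{(1+\rho)/(1-\rho)}/\sqrt{n}} for large n).
#'
#' @param n Series length (>= 16).
#' @param rho Lag-1 autocorrelation in `[0, 1)`.
#' @param marginal_sd Marginal standard deviation.
#' @param mean Planted mean.
#' @param seed Integer seed; deterministic per seed.
#' @return Numeric vector of length `n`.
#' @export
make_ar1_series <- function(n, rho = 0, marginal_sd = 1, mean = 0, seed = 1L) {
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1).",
                                 class = "memcurv_error_domain")
  if (n < 16) abort("`n` must be at least 16.",
                    class = "memcurv_error_insufficient_data")
  if (marginal_sd < 0) abort("`marginal_sd` must be non-negative.",
                             class = "memcurv_error_domain")
  withr::with_seed(seed, {
    innov_sd <- marginal_sd * sqrt(1 - rho^2)
    x0 <- rnorm(1, sd = marginal_sd)
    dev <- stats::filter(rnorm(n, sd = innov_sd), rho,
                         method = "recursive", init = x0)
    # filter() convolves the innovations; x0 seeds the recursion
    mean + as.numeric(dev)
  })
}

#' Generate a coverage-curvature calibration dataset
#'
#' Linear-through-origin points \eqn{y_i = b\,\phi_i + \epsilon_i} with
#' heteroscedastic Gaussian noise of standard deviation `sems[i]`,
#' emulating measured (phi, 2-kappa-m, SEM) calibration data with a known
#' slope.
#'
#' @param slope Planted slope b in kBT/nm.
#' @param phis Area fractions (distinct, in `[0, 1)`).
#' @param sems Per-point noise standard deviations, reported as the SEMs
#'   (> 0, same length as `phis`).
#' @param seed Integer seed; deterministic per seed.
#' @param label Composition tag for the series.
#' @return A coverage-curvature tibble (`label`, `phi`, `two_kappa_m`,
#'   `sem`) ready for [fit_through_origin()].
#' @export
make_coverage_dataset <- function(slope, phis, sems, seed = 1L,
                                  label = "synthetic") {
  if (length(phis) != length(sems)) {
    abort("`phis` and `sems` must have the same length.",
          class = "memcurv_error_format")
  }
  if (any(sems <= 0)) abort("`sems` must be positive.",
                            class = "memcurv_error_domain")
  if (any(phis < 0 | phis >= 1)) abort("`phis` must lie in [0, 1).",
                                       class = "memcurv_error_domain")
  y <- withr::with_seed(seed, slope * phis + rnorm(length(phis), sd = sems))
  tibble(label = label, phi = phis, two_kappa_m = y, sem = sems)
}
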