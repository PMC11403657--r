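test_that("first moment obeys symmetry, closed form and unit conversion", {
  z <- seq(-8, 8, by = 0.01)
  # even profile: zero moment by symmetry
  even <- canonical_profile(z, exp(-z^2 / 2) + 0.3 * exp(-(abs(z) - 2)^2))
  expect_equal(spontaneous_curvature_moment(even), 0, tolerance = 1e-12)

  # s(z) = A z exp(-z^2/2w^2): first moment sqrt(2 pi) A w^3 analytically
  A <- 1; w <- 1
  gauss_odd <- canonical_profile(z, A * z * exp(-z^2 / (2 * w^2)))
  expected_bar_nm2 <- -sqrt(2 * pi) * A * w^3
  expect_equal(expected_bar_nm2, -2.5066, tolerance = 1e-4)
  got <- spontaneous_curvature_moment(gauss_odd)
  expect_equal(got, expected_bar_nm2 * oracle_bar_nm2_to_kbt_per_nm(303.15),
               tolerance = 1e-6)
  expect_equal(got, -0.05989, tolerance = 1e-3)

  # opposite sign convention is a pure sign flip
  expect_equal(spontaneous_curvature_moment(gauss_odd, moment_sign = 1), -got)
  # temperature enters only through kBT
  expect_equal(spontaneous_curvature_moment(gauss_odd, temperature = 310),
               got * 303.15 / 310)
})

test_that("the moment requires a centered, canonically oriented profile", {
  p <- lateral_stress(tibble::tibble(z = seq(0, 8, 0.1), s_lat = 1))
  expect_error(spontaneous_curvature_moment(p), class = "memcurv_error_state")
  expect_error(spontaneous_curvature_moment(center_profile(p)),
               class = "memcurv_error_state")
  expect_silent(spontaneous_curvature_moment(set_orientation(center_profile(p))))
})

test_that("the moment is linear and flips sign under reflection", {
  set.seed(11)
  z <- seq(-6, 6, by = 0.05)
  s1 <- rnorm(length(z)); s2 <- rnorm(length(z))
  m <- function(s) spontaneous_curvature_moment(canonical_profile(z, s))
  expect_equal(m(2 * s1 - 3 * s2), 2 * m(s1) - 3 * m(s2), tolerance = 1e-10)

  p <- canonical_profile(z, s1)
  reflected <- reflect_profile(p)
  attr(reflected, "orientation") <- "exterior-positive"
  expect_equal(m2 <- spontaneous_curvature_moment(reflected), -m(s1))
})

test_that("an upper-leaflet headgroup perturbation shifts the moment one way", {
  z <- seq(-8, 8, by = 0.02)
  base <- exp(-(z - 2)^2 / 0.5) + exp(-(z + 2)^2 / 0.5) - 1.2 * exp(-z^2 / 2)
  bump <- 0.5 * exp(-(z - 2)^2 / 0.32)   # extra repulsion in the upper headgroups
  m0 <- spontaneous_curvature_moment(canonical_profile(z, base))
  m1 <- spontaneous_curvature_moment(canonical_profile(z, base + bump))
  m2 <- spontaneous_curvature_moment(canonical_profile(z, base + 2 * bump))
  expect_lt(m1, m0)   # z-weighted repulsion at positive z lowers -int z s dz
  expect_lt(m2, m1)
  # the same bump on the lower leaflet moves it the other way, symmetrically
  m1_low <- spontaneous_curvature_moment(
    canonical_profile(z, base + 0.5 * exp(-(z + 2)^2 / 0.32)))
  expect_equal(m1_low - m0, -(m1 - m0), tolerance = 1e-9)
})

test_that("moment time series preserve order and demand a common grid", {
  z <- seq(-5, 5, by = 0.1)
  p1 <- canonical_profile(z, z * exp(-z^2))
  expect_equal(moment_timeseries(list(p1)),
               spontaneous_curvature_moment(p1))
  expect_equal(moment_timeseries(rep(list(p1), 5)),
               rep(spontaneous_curvature_moment(p1), 5))
  p_other <- canonical_profile(z + 0.05, z * exp(-z^2))
  expect_error(moment_timeseries(list(p1, p_other)),
               class = "memcurv_error_domain")
  expect_error(moment_timeseries(list()),
               class = "memcurv_error_insufficient_data")
})

test_that("blocking analysis handles degenerate and short input", {
  out <- blocking_sem(rep(3.7, 64))
  expect_equal(out$sem, 0)
  expect_true(out$plateau_found)
  expect_error(blocking_sem(rnorm(15)), class = "memcurv_error_insufficient_data")
  expect_error(blocking_sem(c(rnorm(31), NA)), class = "memcurv_error_format")
})

test_that("blocking on iid data reproduces the naive SEM", {
  sems <- vapply(1:20, function(seed) {
    blocking_sem(make_ar1_series(4096, rho = 0, seed = seed))$sem
  }, double(1))
  expect_equal(mean(sems), 1 / sqrt(4096), tolerance = 0.1)

  # shuffling correlated data must not inflate the estimate
  x <- make_ar1_series(1024, rho = 0.8, seed = 5)
  shuffled <- withr::with_seed(6, sample(x))
  naive <- stats::sd(shuffled) / sqrt(length(shuffled))
  expect_equal(blocking_sem(shuffled)$sem, naive, tolerance = 0.15)
})

test_that("blocking detects autocorrelation that the naive SEM misses", {
  x <- make_ar1_series(16384, rho = 0.9, seed = 3)
  out <- blocking_sem(x)
  naive <- stats::sd(x) / sqrt(length(x))
  analytic <- sqrt((1 + 0.9) / (1 - 0.9)) / sqrt(length(x))
  expect_true(out$plateau_found)
  expect_gt(out$sem, 2 * naive)
  expect_equal(out$sem, analytic, tolerance = 0.25)
})

test_that("area fractions follow the rotating-disk model", {
  expect_equal(area_fraction(ree = 0, box_area = 10.4), 0)
  expect_equal(area_fraction(ree = 2, n_peptides = 1, box_area = 10.4),
               pi / 10.4)
  expect_equal(area_fraction(ree = 1.3, box_area = 14.4),
               2 * area_fraction(ree = 1.3, box_area = 28.8))
  expect_equal(area_fraction(ree = 2, box_area = 10, disk_factor = 0.5),
               pi * 0.25^2 * 4 / 10)
  expect_error(area_fraction(ree = 4, box_area = 10),
               class = "memcurv_error_domain")
  expect_error(area_fraction(ree = -1, box_area = 10),
               class = "memcurv_error_domain")
})

test_that("through-origin fits match exact cases and an independent WLS", {
  one <- curvature_estimate(two_kappa_m = 0.5, sem = 0, phi = 0.1)
  fit1 <- fit_through_origin(one)
  expect_equal(fit1$slope, 5)
  expect_false(fit1$weighted)

  flat <- tibble::tibble(phi = c(0.02, 0.05, 0.1), two_kappa_m = 0,
                         sem = c(0.1, 0.1, 0.2))
  expect_equal(fit_through_origin(flat)$slope, 0)

  set.seed(21)
  d <- tibble::tibble(phi = c(0.02, 0.04, 0.08, 0.12),
                      two_kappa_m = 13 * c(0.02, 0.04, 0.08, 0.12) + rnorm(4, sd = 0.1),
                      sem = c(0.05, 0.08, 0.1, 0.2))
  fit <- fit_through_origin(d, kappa = 25.2)
  lm_w <- stats::lm(two_kappa_m ~ 0 + phi, data = d, weights = 1 / d$sem^2)
  expect_equal(fit$slope, unname(coef(lm_w)), tolerance = 1e-12)
  expect_equal(fit$slope_err, sqrt(1 / sum(d$phi^2 / d$sem^2)), tolerance = 1e-12)
  expect_equal(fit$m0, fit$slope / (2 * 25.2))
  expect_equal(fit$m0 * fit$m0_inv, 1)

  # unweighted path agrees with lm() including the residual-based error
  d0 <- dplyr::mutate(d, sem = 0)
  fit0 <- fit_through_origin(d0)
  lm0 <- summary(stats::lm(two_kappa_m ~ 0 + phi, data = d0))
  expect_equal(fit0$slope, unname(lm0$coefficients[1, 1]), tolerance = 1e-12)
  expect_equal(fit0$slope_err, unname(lm0$coefficients[1, 2]), tolerance = 1e-12)
})

test_that("through-origin fit validates its design", {
  expect_error(fit_through_origin(tibble::tibble(phi = 0, two_kappa_m = 1, sem = 1)),
               class = "memcurv_error_degenerate")
  expect_error(fit_through_origin(
    tibble::tibble(phi = c(0.1, 0.2), two_kappa_m = 1:2, sem = c(0, 1))),
    class = "memcurv_error_format")
  expect_error(fit_through_origin(
    tibble::tibble(phi = c(0.1, 0.1), two_kappa_m = 1:2, sem = c(1, 1))),
    class = "memcurv_error_format")
  expect_error(fit_through_origin(
    tibble::tibble(phi = c(0.1, 0.2), two_kappa_m = 1:2, sem = c(1, 1),
                   label = c("a", "b"))),
    class = "memcurv_error_format")
})

test_that("origin fits are scale-equivariant", {
  d <- make_coverage_dataset(slope = -8, phis = c(0.02, 0.05, 0.09),
                             sems = c(0.05, 0.05, 0.1), seed = 9)
  b <- fit_through_origin(d)$slope
  d_y <- dplyr::mutate(d, two_kappa_m = 3 * two_kappa_m, sem = 3 * sem)
  expect_equal(fit_through_origin(d_y)$slope, 3 * b, tolerance = 1e-12)
  d_x <- dplyr::mutate(d, phi = phi / 2)
  expect_equal(fit_through_origin(d_x)$slope, 2 * b, tolerance = 1e-12)
})

test_that("leaflet flip negates curvatures, preserves errors, commutes with fitting", {
  est <- curvature_estimate(two_kappa_m = -0.4, sem = 0.05, phi = 0.03,
                            label = "POPG 5+")
  flipped <- leaflet_flip(est)
  expect_equal(flipped$two_kappa_m, 0.4)
  expect_equal(flipped$sem, 0.05)
  expect_match(flipped$label, "inner-leaflet")
  back <- leaflet_flip(flipped)
  expect_equal(back$two_kappa_m, est$two_kappa_m)
  expect_equal(back$label, est$label)

  d <- make_coverage_dataset(slope = -8, phis = c(0.02, 0.06),
                             sems = c(0.04, 0.08), seed = 2)
  fit_then_flip <- leaflet_flip(fit_through_origin(d))
  flip_then_fit <- fit_through_origin(leaflet_flip(d))
  expect_equal(fit_then_flip$slope, flip_then_fit$slope, tolerance = 1e-12)
  expect_equal(fit_then_flip$slope_err, flip_then_fit$slope_err, tolerance = 1e-12)
  expect_equal(fit_then_flip$m0, flip_then_fit$m0, tolerance = 1e-12)
})

test_that("tidiers expose the fit in broom shape", {
  d <- make_coverage_dataset(slope = 13.3, phis = c(0.025, 0.05),
                             sems = c(0.05, 0.05), seed = 1, label = "POPC 0")
  fit <- fit_through_origin(d, kappa = 25.2)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  gl <- glance(fit)
  expect_equal(gl$slope, fit$slope)
  expect_equal(gl$m0_inv, 2 * 25.2 / fit$slope)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("curvature estimates validate their fields", {
  expect_error(curvature_estimate(Inf, 0.1, 0.1), class = "memcurv_error_domain")
  expect_error(curvature_estimate(1, -0.1, 0.1), class = "memcurv_error_domain")
  expect_error(curvature_estimate(1, 0.1, 1.0), class = "memcurv_error_domain")
})
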