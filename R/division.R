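#' Peptide-anchor binding model
#'
#' Langmuir-type binding of a His-tagged peptide to NTA-Ni anchor lipids:
#' the dissociation constant sets the occupancy of the anchors, and the
#' anchor mole fraction together with the peptide footprint sets the
#' saturating membrane area fraction
#' \eqn{\phi_{sat} = x_{anchor}\, a_{pep} / a_{lip} < 1}
#' (one peptide per anchor; the dilute regime holds throughout).
#'
#' @param kd Dissociation constant K_d in nM (default 18.5, the measured
#'   affinity of a fluorophore-tagged 6-His peptide for NTA anchor lipids).
#' @param anchor_fraction NTA anchor lipid mole fraction (default 0.03).
#' @param area_per_lipid Area per lipid in nm^2 (default 0.64).
#' @param peptide_area Membrane footprint of one bound peptide in nm^2
#'   (default `pi`, a disk of diameter 2 nm — the scale of a short
#'   membrane-adsorbed peptide).
#' @return A `binding_model` list with the fields above plus `phi_sat`.
#' @export
binding_model <- function(kd = 18.5, anchor_fraction = 0.03,
                          area_per_lipid = 0.64, peptide_area = pi) {
  if (kd <= 0) abort("`kd` must be positive.", class = "memcurv_error_domain")
  if (anchor_fraction <= 0 || anchor_fraction >= 1) {
    abort("`anchor_fraction` must lie in (0, 1).", class = "memcurv_error_domain")
  }
  if (area_per_lipid <= 0) abort("`area_per_lipid` must be positive.",
                                 class = "memcurv_error_domain")
  if (peptide_area <= 0) abort("`peptide_area` must be positive.",
                               class = "memcurv_error_domain")
  phi_sat <- anchor_fraction * peptide_area / area_per_lipid
  if (phi_sat >= 1) {
    abort(sprintf("Saturation area fraction %.3g >= 1: binding model leaves the dilute regime.",
                  phi_sat),
          class = "memcurv_error_config")
  }
  structure(list(kd = kd, anchor_fraction = anchor_fraction,
                 area_per_lipid = area_per_lipid, peptide_area = peptide_area,
                 phi_sat = phi_sat),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("<binding_model: Kd = %.3g nM, %.3g%% anchors, phi_sat = %.4g>\n",
              x$kd, 100 * x$anchor_fraction, x$phi_sat))
  invisible(x)
}

#' Langmuir anchor occupancy and membrane coverage
#'
#' `langmuir_occupancy()` gives the fraction of anchors occupied at a given
#' solution concentration, \eqn{\theta(c) = c/(c + K_d)};
#' `coverage()` scales it to the membrane area fraction
#' \eqn{\phi(c) = \theta(c)\,\phi_{sat}}.
#'
#' @param c Solution concentration(s) in nM, >= 0 (vectorised).
#' @param b A [binding_model()].
#' @return Occupancy theta in `[0, 1)` or area fraction phi in
#'   `[0, phi_sat)`.
#' @examples
#' b <- binding_model()
#' langmuir_occupancy(18.5, b) # 0.5 at c = Kd
#' @export
langmuir_occupancy <- function(c, b = binding_model()) {
  stopifnot(inherits(b, "binding_model"))
  if (any(c < 0)) abort("Concentrations must be non-negative.",
                        class = "memcurv_error_domain")
  c / (c + b$kd)
}

#' @rdname langmuir_occupancy
#' @export
coverage <- function(c, b = binding_model()) {
  langmuir_occupancy(c, b) * b$phi_sat
}

#' Spontaneous curvature at a given coverage
#'
#' Converts a membrane area fraction into a spontaneous curvature using a
#' calibrated coverage-curvature slope: \eqn{m = b\,\phi/(2\kappa)}. The
#' slope is measured with the peptide on the outer leaflet; for a peptide
#' synthesised inside the vesicle and adsorbed at the inner leaflet the
#' sign inverts (`inner_leaflet = TRUE`).
#'
#' @param phi Area fraction(s) in `[0, 1)` (vectorised).
#' @param slope Coverage-curvature slope in kBT/nm: a `curvature_fit` from
#'   [fit_through_origin()] (kappa taken from the fit) or a bare number.
#' @param kappa Bending rigidity in kBT; required when `slope` is numeric,
#'   ignored otherwise.
#' @param inner_leaflet Negate the sign for inner-leaflet adsorption.
#' @return Spontaneous curvature m in 1/um.
#' @export
curvature_from_coverage <- function(phi, slope, kappa = NULL,
                                    inner_leaflet = FALSE) {
  if (any(phi < 0 | phi >= 1)) abort("`phi` must lie in [0, 1).",
                                     class = "memcurv_error_domain")
  if (inherits(slope, "curvature_fit")) {
    kappa <- slope$kappa
    slope <- slope$slope
  }
  if (is.null(kappa) || kappa <= 0) {
    abort("Provide a positive `kappa` (kBT) with a numeric slope.",
          class = "memcurv_error_domain")
  }
  m_per_nm <- slope * phi / (2 * kappa)
  if (inner_leaflet) m_per_nm <- -m_per_nm
  m_per_nm * 1e3   # 1/nm -> 1/um
}

#' Vesicle specification
#'
#' A deflated quasi-spherical vesicle is described by the radius of the
#' sphere carrying the same membrane area, \eqn{R_{ves} = \sqrt{A/4\pi}},
#' and its reduced volume \eqn{v = V / (4\pi R_{ves}^3/3) \in (1/\sqrt2, 1)}.
#' Below v = 1 the vesicle has excess area; within this window it can adopt
#' a two-sphere dumbbell with a closed neck.
#'
#' @param r_ves Vesicle radius R_ves in um (> 0).
#' @param v Reduced volume, in (1/sqrt(2), 1) (default 0.8).
#' @param kappa Bending rigidity in kBT (default 25.2).
#' @param temperature Temperature in K (default 303.15).
#' @return A `vesicle_spec` list.
#' @export
vesicle_spec <- function(r_ves, v = 0.8, kappa = 25.2, temperature = 303.15) {
  if (r_ves <= 0) abort("`r_ves` must be positive.", class = "memcurv_error_domain")
  if (v <= 1 / sqrt(2) || v >= 1) {
    abort("Reduced volume `v` must lie in (1/sqrt(2), 1) for a two-sphere dumbbell to exist.",
          class = "memcurv_error_domain")
  }
  if (kappa <= 0) abort("`kappa` must be positive.", class = "memcurv_error_domain")
  structure(list(r_ves = r_ves, v = v, kappa = kappa,
                 temperature = temperature),
            class = "vesicle_spec")
}

#' Two-sphere dumbbell geometry of a deflated vesicle
#'
#' At the closed-neck limit a deflated vesicle of reduced volume v becomes
#' two spheres of radii R1 >= R2 joined by an ideal neck, conserving
#' membrane area and enclosed volume:
#' \deqn{r_1^2 + r_2^2 = 1, \qquad r_1^3 + r_2^3 = v}
#' in units of R_ves. The smaller reduced radius is found by bracketed
#' root finding on (0, 1/sqrt(2)]; the neck curvature is
#' \eqn{M_{ne} = (1/R_1 + 1/R_2)/2}.
#'
#' @param spec A [vesicle_spec()].
#' @return A `dumbbell_geometry` list: `r1`, `r2` (um), `m_ne` (1/um),
#'   reduced radii `r1_red`, `r2_red`, plus `r_ves`, `v`.
#' @examples
#' g <- dumbbell_radii(vesicle_spec(r_ves = 0.5, v = 0.8))
#' g$m_ne
#' @export
dumbbell_radii <- function(spec) {
  stopifnot(inherits(spec, "vesicle_spec"))
  v <- spec$v
  g <- function(r2) (1 - r2^2)^1.5 + r2^3 - v
  # g(0) = 1 - v > 0, g(1/sqrt 2) = 1/sqrt 2 - v < 0: a sign change exists
  root <- uniroot(g, c(0, 1 / sqrt(2)), tol = 1e-14)
  r2 <- root$root
  # one Newton polish; g'(r2) = 3 r2 (r2 - sqrt(1 - r2^2))
  dg <- 3 * r2 * (r2 - sqrt(1 - r2^2))
  if (is.finite(dg) && dg != 0) r2 <- r2 - g(r2) / dg
  r1 <- sqrt(1 - r2^2)
  m_ne <- (1 / r1 + 1 / r2) / (2 * spec$r_ves)
  structure(list(r1 = r1 * spec$r_ves, r2 = r2 * spec$r_ves,
                 r1_red = r1, r2_red = r2, m_ne = m_ne,
                 r_ves = spec$r_ves, v = v),
            class = "dumbbell_geometry")
}

#' @export
print.dumbbell_geometry <- function(x, ...) {
  cat(sprintf("<dumbbell_geometry: R_ves = %.3g um, v = %.4g>\n", x$r_ves, x$v))
  cat(sprintf("  R1 = %.4g um, R2 = %.4g um, M_ne = %.4g 1/um\n",
              x$r1, x$r2, x$m_ne))
  invisible(x)
}

#' Neck-closure threshold curvature
#'
#' A deflated vesicle deforms into a dumbbell with a stably closed neck
#' once its spontaneous curvature reaches the neck curvature:
#' \eqn{m \ge M_{ne}}. The threshold therefore equals the dumbbell's neck
#' curvature and scales as 1/R_ves at fixed reduced volume.
#'
#' @param g A `dumbbell_geometry` from [dumbbell_radii()].
#' @return The threshold spontaneous curvature m* in 1/um.
#' @export
neck_closure_threshold <- function(g) {
  stopifnot(inherits(g, "dumbbell_geometry"))
  g$m_ne
}

#' Constriction force on a closed membrane neck
#'
#' Once the neck is closed, a spontaneous curvature exceeding the neck
#' curvature squeezes the neck with the force
#' \deqn{f = 8\pi\kappa\,(m - M_{ne}),}
#' reported in pN via the thermal energy at `temperature`. Negative values
#' (m below the neck curvature) indicate the neck is not yet under
#' constriction. This closed form is the single place to change should a
#' different neck-force expression be preferred.
#'
#' @param kappa Bending rigidity in kBT.
#' @param m Spontaneous curvature(s) in 1/um (vectorised).
#' @param m_ne Neck curvature M_ne in 1/um.
#' @param temperature Temperature in K.
#' @return Force(s) in pN.
#' @examples
#' constriction_force(25.2, m = 2, m_ne = 1) # ~2.65 pN per 1/um excess
#' @export
constriction_force <- function(kappa, m, m_ne, temperature = 303.15) {
  if (kappa <= 0) abort("`kappa` must be positive.", class = "memcurv_error_domain")
  f_kbt_per_nm <- 8 * pi * kappa * (m - m_ne) * 1e-3   # 1/um -> 1/nm
  f_kbt_per_nm * kbt_per_nm_to_pn(temperature)
}

#' Predict vesicle division from peptide concentration
#'
#' Composes the full chain for a peptide synthesised inside a vesicle and
#' adsorbed at the inner leaflet: solution concentration c is mapped to
#' membrane coverage by the Langmuir model, coverage to spontaneous
#' curvature by the calibrated slope (sign-flipped to the inner leaflet),
#' and curvature to the constriction force on the closed neck of the
#' two-sphere dumbbell. Two thresholds are solved by bracketed root
#' finding on the concentration axis:
#' `c_dumbbell`, where m(c) reaches the neck curvature M_ne (the vesicle
#' deforms into a dumbbell with a closed neck; the force crosses zero
#' exactly here), and `c_at_force`, where the force reaches `f_target`.
#' Each is `NA` when not attained on the grid. Every grid point is labelled
#' `below-neck-closure` (m < m*), `closed-neck-stable` (m >= m*, f <
#' f_target) or `fission-favored` (f >= f_target).
#'
#' If the calibrated slope gives non-positive inner-leaflet curvature
#' everywhere, the prediction is returned with absent thresholds and an
#' explanatory `status` rather than an error.
#'
#' @param b A [binding_model()].
#' @param slope A `curvature_fit` (outer-leaflet calibration) or a bare
#'   numeric slope in kBT/nm (then kappa is taken from `spec`).
#' @param spec A [vesicle_spec()].
#' @param c_grid Increasing concentration grid in nM. Default: 200
#'   log-spaced points spanning `kd/100` to `1000 kd` (binding spans
#'   decades).
#' @param f_target Reference force in pN (default 20, the scale at which
#'   spontaneous neck fission has been observed for His-tagged proteins on
#'   giant vesicles); a configurable reference, not a fission claim.
#' @return A `division_prediction` object; its `curve` is a tibble
#'   (`c_nM`, `phi`, `m_per_um`, `f_pN`, `regime`), with scalars
#'   `c_dumbbell`, `c_at_force`, `m_star`, `status` and the input
#'   parameters attached. See [tidy()][generics::tidy],
#'   [glance()][generics::glance] and [autoplot()][ggplot2::autoplot]
#'   methods.
#' @examples
#' fit_slope <- -13 # kBT/nm, outer-leaflet calibration of a charged peptide
#' pred <- predict_division(binding_model(), fit_slope,
#'                          vesicle_spec(r_ves = 0.5))
#' glance(pred)
#' @export
predict_division <- function(b, slope, spec, c_grid = NULL, f_target = 20) {
  stopifnot(inherits(b, "binding_model"), inherits(spec, "vesicle_spec"))
  if (inherits(slope, "curvature_fit")) {
    kappa <- slope$kappa
    slope_val <- slope$slope
  } else {
    kappa <- spec$kappa
    slope_val <- as.double(slope)
  }
  if (is.null(c_grid)) {
    c_grid <- exp(seq(log(b$kd / 100), log(b$kd * 1000), length.out = 200L))
  }
  if (is.unsorted(c_grid, strictly = TRUE) || any(c_grid < 0)) {
    abort("`c_grid` must be non-negative and strictly increasing.",
          class = "memcurv_error_domain")
  }
  geom <- dumbbell_radii(spec)
  m_star <- neck_closure_threshold(geom)
  m_of <- function(c) curvature_from_coverage(coverage(c, b), slope_val,
                                              kappa = kappa,
                                              inner_leaflet = TRUE)
  f_of <- function(c) constriction_force(kappa, m_of(c), m_star,
                                         temperature = spec$temperature)
  phi <- coverage(c_grid, b)
  m <- m_of(c_grid)
  f <- f_of(c_grid)

  c_max <- max(c_grid)
  status <- "ok"
  c_dumbbell <- NA_real_
  c_at_force <- NA_real_
  if (max(m) <= 0) {
    status <- "inner-leaflet curvature non-positive on the grid: no neck closure at any concentration"
  } else {
    solve_c <- function(fun, target) {
      lo <- min(c_grid)
      if (fun(lo) - target > 0) return(lo)
      if (fun(c_max) - target < 0) return(NA_real_)
      uniroot(function(c) fun(c) - target, c(lo, c_max),
              tol = 1e-10 * c_max, maxiter = 200L)$root
    }
    c_dumbbell <- solve_c(m_of, m_star)
    c_at_force <- solve_c(f_of, f_target)
    if (is.na(c_dumbbell)) {
      status <- "neck-closure threshold not reached on the concentration grid"
    }
  }
  regime <- dplyr::case_when(
    m < m_star ~ "below-neck-closure",
    f < f_target ~ "closed-neck-stable",
    .default = "fission-favored"
  )
  curve <- tibble(c_nM = c_grid, phi = phi, m_per_um = m, f_pN = f,
                  regime = regime)
  structure(
    list(curve = curve, c_dumbbell = c_dumbbell, c_at_force = c_at_force,
         m_star = m_star, f_target = f_target, status = status,
         binding = b, geometry = geom, spec = spec,
         slope = slope_val, kappa = kappa),
    class = "division_prediction"
  )
}

#' @export
print.division_prediction <- function(x, ...) {
  cat(sprintf("<division_prediction: R_ves = %.3g um, v = %.4g, slope = %.4g kBT/nm>\n",
              x$spec$r_ves, x$spec$v, x$slope))
  cat(sprintf("  neck-closure threshold m* = %.4g 1/um\n", x$m_star))
  cat(sprintf("  c(dumbbell)   = %s nM\n", format(x$c_dumbbell, digits = 4)))
  cat(sprintf("  c(f = %.3g pN) = %s nM\n", x$f_target,
              format(x$c_at_force, digits = 4)))
  if (x$status != "ok") cat("  status:", x$status, "\n")
  invisible(x)
}

#' Tidy, summarise and plot division predictions
#'
#' @param x,object A `division_prediction` from [predict_division()].
#' @param ... Unused.
#' @return `tidy()`: the per-concentration curve as a tibble; `glance()`:
#'   a one-row tibble of thresholds and parameters; `autoplot()`: a ggplot
#'   of constriction force versus concentration with regime colouring.
#' @export
tidy.division_prediction <- function(x, ...) x$curve

#' @rdname tidy.division_prediction
#' @export
glance.division_prediction <- function(x, ...) {
  tibble(c_dumbbell_nM = x$c_dumbbell, c_at_force_nM = x$c_at_force,
         m_star_per_um = x$m_star, f_target_pN = x$f_target,
         r_ves_um = x$spec$r_ves, v = x$spec$v, kappa_kBT = x$kappa,
         slope_kBT_per_nm = x$slope, kd_nM = x$binding$kd,
         phi_sat = x$binding$phi_sat, status = x$status)
}

#' @rdname tidy.division_prediction
#' @export
autoplot.division_prediction <- function(object, ...) {
  gg <- ggplot2::ggplot(object$curve,
                        ggplot2::aes(x = .data$c_nM, y = .data$f_pN)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_hline(yintercept = object$f_target, colour = "grey40",
                        linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(colour = .data$regime, group = 1)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "solution concentration (nM)",
                  y = "neck constriction force (pN)",
                  colour = NULL,
                  title = sprintf("R_ves = %.3g um, v = %.3g",
                                  object$spec$r_ves, object$spec$v))
  if (!is.na(object$c_dumbbell)) {
    gg <- gg + ggplot2::geom_vline(xintercept = object$c_dumbbell,
                                   linetype = "dashed", colour = "grey40")
  }
  gg
}
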