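---
title: "From lateral stress profiles to division-from-within predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From lateral stress profiles to division-from-within predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memcurv)
```

`memcurv` chains five pieces of membrane physics: (i) the spontaneous
curvature of an asymmetric bilayer from the first moment of its lateral
stress profile, (ii) blocking-analysis error bars for that estimate,
(iii) a through-origin calibration of curvature against peptide coverage,
(iv) Langmuir binding that maps solution concentration to coverage, and
(v) the two-sphere dumbbell geometry of a deflated vesicle with the
constriction force on its closed neck. This vignette records the model
assumptions, the numerical choices, and what the synthetic-data tests do
and do not demonstrate.

## The first moment and its sign

For a planar bilayer with lateral stress profile
$s(z) = (\sigma_{xx}+\sigma_{yy})/2 - \sigma_{zz}$, the product of bending
rigidity and spontaneous curvature is

$$2\kappa m \;=\; -\int z\, s(z)\, \mathrm{d}z,$$

with $z=0$ at the bilayer midplane and the exterior solution at positive
$z$ (the membrane normal points from the upper leaflet into the exterior).
Under this convention a membrane that bulges toward the exterior
compartment has $m > 0$. The sign of the integral is the one genuinely
convention-dependent choice in the pipeline: it is fixed so that extra
lateral *repulsion* in the upper (exterior-facing) leaflet — a bulky
adsorbed peptide pushing the headgroups apart — drives $2\kappa m$
*negative*, i.e. bending away from the peptide, which matches the verbal
semantics above. Users whose upstream stress tool emits the opposite sign
can set `moment_sign = +1` in `spontaneous_curvature_moment()` rather than
editing data.

Assumptions inherited from the moment formula: the bilayer is planar,
tension-free, and the stress profile is laterally averaged. `tension()`
checks the zeroth moment $\int s\,\mathrm{d}z$ and warns beyond
1 bar·nm — a warning, not an error, because finite sampling always leaves
residual tension.

Orientation and centering are explicit states, not guesses:
`center_profile()` defaults the midplane to the geometric box center
(membrane drift correction belongs upstream), and `set_orientation()`
reflects the grid when the exterior was recorded at negative $z$.
`spontaneous_curvature_moment()` refuses profiles whose state flags are
not canonical, which catches the classic silent sign error.

## Quadrature and units

Integration is trapezoidal on the native grid. Tabulated stress profiles
are already smoothed by slab averaging; interpolating them adds model
error that is hard to audit, so non-uniform grids are rejected instead of
resampled. For the smooth, rapidly decaying profiles this pipeline deals
with, trapezoid error is far below statistical error (the test suite
compares against adaptive quadrature at $10^{-6}$ relative).

Inputs are bar and nm (the convention of local-stress tools); results are
$k_BT$/nm. The conversion is computed from the Boltzmann constant at the
requested temperature — default 303.15 K, the simulation temperature of
the calibration systems — giving 1 bar·nm² ≈ 0.02389 $k_BT$/nm and
1 $k_BT$/nm ≈ 4.185 pN. Nothing is hard-coded; pass `temperature` to
change it.

## Blocking analysis

Per-block first moments are autocorrelated, so the naive SEM
underestimates. `blocking_sem()` implements Flyvbjerg–Petersen blocking:
average neighbour pairs, re-estimate $s_k = \sqrt{c_k/(n_k-1)}$ at each
level ($c_k$ the population variance of the $n_k$ blocks), and stop at the
first *plateau* — the first level whose estimate lies within its own
one-sigma uncertainty $s_k/\sqrt{2(n_k-1)}$ of the next level's. The
plateau rule is a design choice (the method itself prescribes none); the
first-plateau variant is conservative against over-blocking noise at deep
levels. When no plateau occurs the maximum across levels is returned with
`plateau_found = FALSE`, which should be read as a lower bound on the true
SEM, and blocking stops once fewer than `min_blocks = 4` blocks remain
(variances from fewer blocks are too noisy to compare). Calibration in the
test suite: on iid data the estimate matches $\sigma/\sqrt{N}$ within a
few percent on average; on AR(1) data with $\rho = 0.9$ it matches the
analytic $\sigma\sqrt{(1+\rho)/(1-\rho)}/\sqrt{N}$ within its expected
scatter.

## Coverage and the through-origin fit

The peptide's covered area is modelled as a disk whose *diameter* equals
the mean end-to-end distance (the lipid:anchor complex rotates freely, so
the covered area is circular). Diameter-equals-extent is the minimal
reading of that geometry; `disk_factor` rescales it if a different
footprint convention is preferred. `area_fraction()` refuses results at or
above 1: the whole calibration lives in the dilute regime.

A symmetric membrane has $m = 0$, so the calibration line
$2\kappa m = b\,\phi$ is fitted *through the origin*. With per-point SEMs
the fit is weighted by $1/\mathrm{sem}^2$ — points measured at different
coverages have different uncertainty and should not count equally — and
the slope error is the exact $(\sum w_i x_i^2)^{-1/2}$ of known-variance
weighted least squares. Without SEMs the unweighted estimator with the
residual-based error is used; mixing the two is an error rather than a
guess. The slope divided by $2\kappa$ gives the curvature per unit
coverage $m_0$ and the local curvature radius $1/m_0$; $\kappa$ is an
*input* (default 25.2 $k_BT$) — estimating it from fluctuations is out of
scope, and comparisons of $2\kappa m$ across lipid compositions should
remember that $\kappa$ itself varies with composition.

`leaflet_flip()` encodes that adsorbing the same species at the inner
leaflet mirrors the asymmetry: curvatures negate, uncertainties are
untouched. Flipping commutes with fitting, which the suite checks.

## Binding and saturation

Coverage versus solution concentration is a Langmuir isotherm
$\theta(c) = c/(c+K_d)$ scaled by the saturation coverage
$\phi_{sat} = x_{anchor}\, a_{pep}/a_{lip}$ — one peptide per anchor
lipid, each contributing its footprint. Defaults: $K_d = 18.5$ nM (the
measured affinity of a fluorophore-tagged 6-His peptide for NTA anchor
lipids), 3 mol% anchors, 0.64 nm² per lipid, and a π nm² footprint (disk
of 2 nm diameter, the scale of a short adsorbed peptide), giving
$\phi_{sat} \approx 0.147$ — comfortably dilute, consistent with
neglecting peptide–peptide interactions. The saturation model is the one
place where the calibration and the prediction are stitched together with
an assumption rather than a measurement; all four numbers are plain
arguments to `binding_model()`.

## Dumbbell geometry, thresholds, and force

A vesicle with membrane area $A = 4\pi R_{ves}^2$ and reduced volume
$v \in (1/\sqrt2, 1)$ can close into two spheres ($r_1^2 + r_2^2 = 1$,
$r_1^3 + r_2^3 = v$ in units of $R_{ves}$) joined by an ideal neck of
curvature $M_{ne} = (1/R_1 + 1/R_2)/2$. The small radius is found by
bracketed root finding on $(0, 1/\sqrt2]$ (`uniroot` at $10^{-14}$
tolerance plus one Newton polish; constraint residuals are below
$10^{-10}$ across the domain, machine precision in practice). The neck
closes when $m \ge M_{ne}$, and beyond closure the neck is squeezed with

$$f = 8\pi\kappa\,(m - M_{ne}),$$

about 2.65 pN per $\mu m^{-1}$ of curvature excess at $\kappa = 25.2\,
k_BT$. This closed form is isolated in `constriction_force()` as the
single place to change if a different neck-force expression is preferred.
Below threshold the formula goes negative; `predict_division()` keeps the
signed value (its zero crossing *is* the dumbbell threshold) and labels
regimes instead: `below-neck-closure`, `closed-neck-stable`, and
`fission-favored` beyond `f_target`. The default `f_target = 20` pN is a
reference anchored to the force scale at which spontaneous neck fission of
giant vesicles has been observed for His-tagged proteins — a configurable
marker, not a claim about the exact fission force. The default reduced
volume $v = 0.8$ and vesicle radii of 0.5 and 10 µm bracket the cell-sized
regime of interest; only the two-sphere closed-neck limit is solved (full
axisymmetric shape equations are out of scope).

Concentration thresholds are solved by bracketed root finding on the span
of the (log-spaced by default — binding spans decades) concentration grid,
to well below 0.1 % relative error. A calibration whose inner-leaflet
curvature never turns positive yields a prediction with absent thresholds
and an explanatory `status`, not an exception: "this peptide cannot divide
this vesicle" is a result.

## What the synthetic data emulate — and what they do not

The generators exist so every stage has known ground truth:

* `make_profile_ensemble()` builds tension-free profiles — symmetric
  headgroup peaks balanced by a midplane trough so the discrete zeroth
  moment is exactly zero — plus an antisymmetric lobe scaled so the
  discrete first moment equals the planted value exactly, then adds white
  Gaussian per-slab noise per frame. Defaults (16 nm box, 0.1 nm slabs,
  peaks at ±2 nm, widths 0.5–1 nm, amplitudes ~100 bar) mimic the *scale*
  of coarse-grained bilayer stress profiles, nothing more.
* `make_ar1_series()` provides stationary AR(1) series whose
  mean-of-series SEM is known analytically — the standard blocking-analysis
  calibration instrument.
* `make_coverage_dataset()` draws through-origin points with
  heteroscedastic Gaussian noise at the stated SEMs.

Passing tests therefore show the *estimators* are correct and calibrated.
They do not show that real coarse-grained profiles are white-noise
perturbations of a three-Gaussian shape (they are not: slab noise is
correlated, profiles have more structure), nor do they validate the
force-field, the binding constant, or the saturation model against
experiments. Problem sizes used in the checks — 100-seed ensembles of 400
frames, 200 iid series of 4096 points, AR(1) series of 65536 points, 500
fit replicates, 1000 geometry draws — were chosen so each estimator's
sampling error is several times smaller than the tolerance being checked.

## Known limitations

* $\kappa$ is a single input per composition; charge-dependent rigidity
  and ionic-asymmetry contributions to $m$ are not disentangled.
* The coverage–curvature line is extrapolated linearly from dilute
  calibration points; high-coverage curvature is outside the model.
* The neck force uses the ideal two-sphere closed-neck limit; prolate
  intermediates and energy barriers between branches are not computed.
* pH-dependent His charge states (and hence anchoring strength) are not
  modelled; the calibration slope is whatever the user supplies.
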