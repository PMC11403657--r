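# Shared fixtures and independent oracles for the test suite.

# Canonical profile: centered, exterior at positive z.
canonical_profile <- function(z, s) {
  stress_profile(z, s, orientation = "exterior-positive", centered = TRUE)
}

# Independent thermal-energy conversion built from the Boltzmann constant,
# used to cross-check the package's unit chain.
oracle_bar_nm2_to_kbt_per_nm <- function(temperature) {
  kB <- 1.380649e-23                    # J/K
  (1e5 * 1e-18 * 1e-9) / (kB * temperature)   # bar nm^2 -> J -> kBT, per nm
}
oracle_kbt_per_nm_to_pn <- function(temperature) {
  kB <- 1.380649e-23
  kB * temperature / 1e-9 * 1e12
}

# Analytic profile family used for the quadrature-oracle comparisons:
# symmetric headgroup peaks + balanced trough + an antisymmetric lobe.
analytic_profile_fun <- function(ap, at, zh, wp, wt, codd, wodd) {
  function(z) {
    ap * (exp(-(z - zh)^2 / (2 * wp^2)) + exp(-(z + zh)^2 / (2 * wp^2))) -
      at * exp(-z^2 / (2 * wt^2)) +
      codd * z * exp(-z^2 / (2 * wodd^2))
  }
}

# Brute-force bisection for the two-sphere dumbbell (independent of the
# package's root finder).
oracle_dumbbell_r2 <- function(v, tol = 1e-13) {
  lo <- 1e-9
  hi <- 1 / sqrt(2)
  g <- function(r2) (1 - r2^2)^1.5 + r2^3 - v
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Write a table of lines to a temp file, returning the path.
write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".dat",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
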