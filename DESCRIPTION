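Package: memcurv
Title: Membrane Spontaneous Curvature from Lateral Stress Profiles and
    Peptide-Driven Vesicle Division Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline turning coarse-grained bilayer lateral-stress
    profiles and peptide-binding parameters into predictions of vesicle
    division from within. Reads per-slab local-stress tables, estimates the
    spontaneous-curvature parameter 2*kappa*m from the first moment of the
    lateral stress profile with blocking-analysis standard errors, fits the
    coverage-curvature relation through the origin, maps peptide solution
    concentration to membrane coverage via a Langmuir isotherm, solves the
    two-sphere dumbbell-vesicle neck geometry, and evaluates neck-closure
    thresholds and constriction forces. Includes synthetic-data generators
    with planted ground truth so every stage is testable without external
    simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
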