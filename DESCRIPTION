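Package: hydrolayer
Title: Layer-Resolved Vibrational and Infrared Spectra of Hydration Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect the hydration shell of a solvated biomolecule
    layer by layer from molecular-dynamics trajectories that store velocities.
    Computes radial water density profiles with periodic Voronoi cell volumes,
    partitions the hydration shell into sub-layers at density extrema, selects
    per-layer water populations by a residence-time criterion, and derives
    per-layer and cumulative vibrational densities of states (from velocity
    autocorrelation functions) and infrared spectra (from the autocorrelation
    of the dipole-moment time derivative), with band summaries and plotting.
    Includes seeded synthetic-trajectory generators (harmonic modes,
    Ornstein-Uhlenbeck gases, layered density boxes) with known analytic
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
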