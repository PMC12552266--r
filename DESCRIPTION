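Package: hydrosol
Title: Equivalent Radii, Spheroid Hydrodynamics and Sedimentation-Velocity
    Analysis for Macromolecules in Dilute Solution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dilute-solution hydrodynamics of macromolecules and
    nanoparticles. Converts measured solution properties (diffusion and
    sedimentation coefficients, intrinsic viscosity, radius of gyration) into
    equivalent hydrodynamic radii and their dimensionless ratios, evaluates the
    classical universal parameters (Flory, Scheraga-Mandelkern, Tsvetkov), and
    provides exact Perrin and Simha shape functions for revolution ellipsoids
    together with wormlike-chain geometry. Includes a global-fit statistic for
    multi-species, multi-property datasets, forward models of sedimentation
    velocity (an analytic no-diffusion boundary, a Brownian-dynamics particle
    simulator, and a finite-volume Lamm-equation solver), and a two-dimensional
    non-negative least-squares inversion of sedimentation scans on a grid of
    hydrodynamic radius and buoyant mass.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
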