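ctx <- solvent_context(293.15, 0.01002, 0.998)

test_that("translational radius agrees across all three sources", {
  ## Stokes identity
  f <- 6 * pi * ctx$eta0 * 1e-7
  expect_equal(translational_radius(f = f, ctx = ctx), 1e-7)
  ## from D (frozen value computed from kB*T/(6 pi eta0 D))
  expect_rel_equal(translational_radius(D = 2.1429e-6, ctx = ctx),
                   1.000006e-7, 1e-5)
  ## from s: generate s from a known radius and invert
  sol <- solute_spec(M = 5e4, vbar = 0.73)
  obs <- observables_from_radii(c(aT = 3e-7), ctx, sol)
  expect_equal(translational_radius(s = obs$s, ctx = ctx, solute = sol),
               3e-7, tolerance = 1e-12)
  expect_error(translational_radius(D = 1e-6, f = 1e-7, ctx = ctx),
               "exactly one")
})

test_that("intrinsic diffusion coefficient matches the printed 7.32e-18/aT", {
  for (aT in c(1e-7, 3.3e-7, 2e-6)) {
    D <- .kB * ctx$T / (6 * pi * ctx$eta0 * aT)
    expect_rel_equal(D * ctx$eta0 / ctx$T, 7.32e-18 / aT, 1e-3)
  }
})

test_that("viscometric radius round-trips through the sphere formula", {
  ## sphere of R = 2e-7 cm, M = 1e5 Da has [eta] = 0.5045 cm^3/g
  eta <- intrinsic_viscosity(2e-7, 1e5)
  expect_rel_equal(eta, 0.5045, 1e-4)
  expect_equal(viscometric_radius(eta, 1e5), 2e-7, tolerance = 1e-12)
  ## random positive round trips
  set.seed(4)
  for (k in 1:20) {
    aI <- 10^runif(1, -7.5, -5.5); M <- 10^runif(1, 3.5, 7)
    expect_equal(viscometric_radius(intrinsic_viscosity(aI, M), M), aI,
                 tolerance = 1e-12)
  }
})

test_that("gyration and volume equivalent radii match their definitions", {
  expect_rel_equal(gyration_equivalent_radius(1), 1.291, 1e-3)
  ## solid sphere: Rg = sqrt(3/5) R recovers R
  expect_equal(gyration_equivalent_radius(sqrt(3 / 5) * 2e-7), 2e-7,
               tolerance = 1e-14)
  ## ratio independent of Rg
  expect_equal(gyration_equivalent_radius(5) / 5,
               gyration_equivalent_radius(0.1) / 0.1)
  expect_rel_equal(volume_equivalent_radius(1e5, 0.73), 3.07e-7, 2e-3)
  expect_equal(volume_equivalent_radius(1e5, 2 * 0.73) /
                 volume_equivalent_radius(1e5, 0.73), 2^(1 / 3))
  ## definition inverse: (4 pi/3) aV^3 = M vbar / NA
  aV <- volume_equivalent_radius(2e5, 0.71)
  expect_equal(4 * pi / 3 * aV^3, 2e5 * 0.71 / physical_constants()$N_A,
               tolerance = 1e-12)
})

test_that("radii ratios obey the combination identity and sphere limit", {
  r <- c(aT = 2e-7, aI = 2e-7, aG = 2e-7, aV = 2e-7)
  rt <- radii_ratios(r)
  expect_equal(unlist(rt), c(IT = 1, GT = 1, GI = 1, TV = 1, IV = 1))
  ## IT = GT/GI
  rt2 <- radii_ratios(c(aT = 1e-7, aI = 1.075e-7, aG = 1.655e-7))
  expect_equal(rt2$IT, rt2$GT / rt2$GI, tolerance = 1e-12)
  expect_rel_equal(radii_ratios(c(aT = 1e-7, aG = 1.655e-7,
                                  aI = 1.655e-7 / 1.539))$IT, 1.075, 1e-3)
  expect_error(radii_ratios(c(aT = 1e-7)), "At least two")
})

test_that("property -> radius -> property round trips are exact", {
  sol <- solute_spec(M = 1.2e5, vbar = 0.74)
  radii <- c(aT = 2.4e-7, aI = 2.6e-7, aG = 3.4e-7)
  obs <- observables_from_radii(radii, ctx, sol)
  expect_equal(translational_radius(D = obs$D, ctx = ctx), radii[["aT"]],
               tolerance = 1e-12)
  expect_equal(translational_radius(s = obs$s, ctx = ctx, solute = sol),
               radii[["aT"]], tolerance = 1e-12)
  expect_equal(viscometric_radius(obs$eta_intr, sol$M), radii[["aI"]],
               tolerance = 1e-12)
  expect_equal(gyration_equivalent_radius(obs$Rg), radii[["aG"]],
               tolerance = 1e-12)
})

test_that("s*eta0 equals 0.053 mb/aT and flotation flips the sign of s", {
  sol <- solute_spec(M = 5e4, vbar = 0.73)
  obs <- observables_from_radii(c(aT = 2e-7), ctx, sol)
  mb <- sol$M * (1 - sol$vbar * ctx$rho) / physical_constants()$N_A
  expect_rel_equal(obs$s * ctx$eta0, 0.053 * mb / 2e-7, 2e-2)
  dense_solvent <- solvent_context(293.15, 0.01002, 1.6)
  obs2 <- observables_from_radii(c(aT = 2e-7), dense_solvent, sol)
  expect_lt(obs2$s, 0)
})

test_that("equivalent radii are solvent-invariant for a fixed particle", {
  sol <- solute_spec(M = 8e4, vbar = 0.72)
  ctx2 <- solvent_context(310.15, 0.0069, 1.005)
  for (cx in list(ctx, ctx2)) {
    obs <- observables_from_radii(c(aT = 2.2e-7, aI = 2.4e-7, aG = 3e-7),
                                  cx, sol)
    props <- tibble::tibble(
      species = "x",
      property = c("D", "s", "eta_intr", "Rg", "M", "vbar"),
      value = c(obs$D, obs$s, obs$eta_intr, obs$Rg, sol$M, sol$vbar))
    rr <- equivalent_radii(props, cx)
    expect_equal(rr$value[rr$radius == "aT"], 2.2e-7, tolerance = 1e-10)
    expect_equal(rr$value[rr$radius == "aI"], 2.4e-7, tolerance = 1e-10)
    expect_equal(rr$value[rr$radius == "aG"], 3e-7, tolerance = 1e-10)
  }
})

test_that("equivalent_radii records provenance and propagates uncertainty", {
  props <- tibble::tibble(
    species = "x", property = c("D", "M", "vbar"),
    value = c(1.06e-6, 14300, 0.703), unit = NA_character_,
    sigma = c(0.02e-6, NA, NA))
  rr <- equivalent_radii(props, ctx)
  aT <- rr[rr$radius == "aT", ]
  expect_identical(aT$provenance, "measured-from-D")
  expect_equal(aT$sigma / aT$value, 0.02 / 1.06, tolerance = 1e-10)
  expect_error(
    equivalent_radii(tibble::tibble(species = "x", property = "Dx",
                                    value = 1), ctx),
    "Unknown property")
})

test_that("universal parameters take the printed sphere and coil values", {
  up <- universal_parameters(ratios = c(IT = 1, GT = 1, GI = 1))
  expect_rel_equal(up$P0, 9.93, 1e-2)
  expect_rel_equal(up$Phi, 9.23e23, 1e-2)
  expect_rel_equal(up$beta, 2.112e6, 1e-2)
  ## good-solvent beta from P0 = 5.3 and Phi = 1.9e23
  beta_good <- (1.9e23)^(1 / 3) / (100^(1 / 3) * 5.3)
  expect_rel_equal(beta_good, 2.34e6, 1e-2)
  ## A0 = kB * beta always
  expect_equal(up$A0, physical_constants()$k_B * up$beta)
})

test_that("universal parameters agree between raw and ratio routes", {
  set.seed(11)
  for (k in 1:10) {
    p <- 10^runif(1, -1, 1)
    aV <- 10^runif(1, -7, -6)
    r <- spheroid_radii(spheroid(p = p, aV = aV))
    M <- 4 * pi / 3 * aV^3 * physical_constants()$N_A / 0.73
    sol <- solute_spec(M = M, vbar = 0.73)
    obs <- observables_from_radii(c(aT = r$aT, aI = r$aI, aG = r$aG),
                                  ctx, sol)
    raw <- universal_parameters(
      props = c(D = obs$D, s = obs$s, eta_intr = obs$eta_intr, Rg = obs$Rg),
      solute = sol, ctx = ctx)
    rat <- universal_parameters(
      ratios = radii_ratios(c(aT = r$aT, aI = r$aI, aG = r$aG)))
    expect_rel_equal(raw$P0, rat$P0, 1e-10)
    expect_rel_equal(raw$Phi, rat$Phi, 1e-10)
    expect_rel_equal(raw$beta, rat$beta, 1e-10)
  }
})

test_that("molecular weight estimators behave as specified", {
  ## exact sphere analysed with IT_assumed = 1.05 overestimates by 1.05^3
  sol <- solute_spec(M = 1e5, vbar = 0.73)
  R <- volume_equivalent_radius(sol$M, sol$vbar)
  obs <- observables_from_radii(c(aT = R, aI = R), ctx, sol)
  Md <- molecular_weight_estimate(D = obs$D, eta_intr = obs$eta_intr,
                                  ctx = ctx)
  expect_rel_equal(Md / sol$M, 1.05^3, 1e-10)
  ## for a particle whose true IT equals the assumed 1.05, Svedberg-linked
  ## s and D make the two forms coincide with the true M
  obs105 <- observables_from_radii(c(aT = R, aI = 1.05 * R), ctx, sol)
  Md105 <- molecular_weight_estimate(D = obs105$D,
                                     eta_intr = obs105$eta_intr, ctx = ctx)
  Ms105 <- molecular_weight_estimate(s = obs105$s,
                                     eta_intr = obs105$eta_intr,
                                     ctx = ctx, vbar = sol$vbar)
  expect_rel_equal(Md105, Ms105, 1e-10)
  expect_rel_equal(Md105, sol$M, 1e-10)
  Ms <- molecular_weight_estimate(s = obs$s, eta_intr = obs$eta_intr,
                                  ctx = ctx, vbar = sol$vbar)
  ## Svedberg M is exact and eta0-independent
  expect_rel_equal(svedberg_molecular_weight(obs$s, obs$D, sol, ctx),
                   sol$M, 1e-12)
  ctx_thick <- solvent_context(293.15, 0.05, 0.998)
  obs2 <- observables_from_radii(c(aT = R), ctx_thick, sol)
  expect_rel_equal(svedberg_molecular_weight(obs2$s, obs2$D, sol, ctx_thick),
                   sol$M, 1e-12)
  ## agreement with the approximate estimator bounded by the IT^3 ratio
  expect_lt(abs(Md / sol$M - 1), 1.05^3 - 1 + 1e-9)
})

test_that("hydrated frictional ratio equals TV and responds to hydration", {
  sol <- solute_spec(M = 5e4, vbar = 0.73, delta = 0)
  aV <- volume_equivalent_radius(sol$M, sol$vbar)
  f0 <- 6 * pi * ctx$eta0 * aV
  expect_equal(frictional_ratio_hydrated(f0, sol, ctx), 1,
               tolerance = 1e-12)
  set.seed(21)
  for (k in 1:10) {
    f <- f0 * runif(1, 1, 3)
    delta <- runif(1, 0, 0.5)
    solh <- solute_spec(sol$M, sol$vbar, delta)
    vbar_h <- sol$vbar + delta / ctx$rho
    aVh <- volume_equivalent_radius(sol$M, vbar_h)
    expect_equal(frictional_ratio_hydrated(f, solh, ctx),
                 (f / (6 * pi * ctx$eta0)) / aVh, tolerance = 1e-12)
  }
  ## delta > 0 lowers f/f0 at fixed f (larger reference sphere)
  expect_lt(frictional_ratio_hydrated(2 * f0, solute_spec(5e4, 0.73, 0.4),
                                      ctx),
            frictional_ratio_hydrated(2 * f0, sol, ctx))
})

test_that("neutral buoyancy raises a dedicated error", {
  sol <- solute_spec(M = 5e4, vbar = 1 / 0.998)
  expect_error(translational_radius(s = 5e-13, ctx = ctx, solute = sol),
               "Neutral buoyancy")
  expect_error(svedberg_molecular_weight(5e-13, 1e-6, sol, ctx),
               "Neutral buoyancy")
})
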