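ctx <- water20()
geom <- std_cell()

test_that("analytic boundary motion follows ln(r/rm) = w^2 s t", {
  run <- rotor_run(rpm = 50000, scan_times_s = c(0, 3600))
  expect_equal(boundary_position_analytic(5e-13, run, geom, 0), geom$r_m,
               ignore_attr = TRUE)
  ## frozen: 6.0 * exp(5236^2 * 5e-13 * 3600) = 6.3035 cm
  r1h <- boundary_position_analytic(5e-13, run, geom, 3600)
  expect_rel_equal(as.numeric(r1h), 6.3035, 1e-4)
  ## linearity of ln(r/rm) in t with slope w^2 s
  tt <- seq(0, 5000, by = 500)
  lr <- log(as.numeric(
    boundary_position_analytic(4e-13, run, geom, tt)) / geom$r_m)
  slopes <- diff(lr) / diff(tt)
  expect_rel_equal(slopes, run$omega^2 * 4e-13, 1e-12)
  ## pellet clipping
  rp <- boundary_position_analytic(5e-12, run, geom, 3600)
  expect_equal(as.numeric(rp), geom$r_b)
  expect_true(attr(rp, "pelleted"))
})

test_that("species coefficients satisfy s*f = mb and Stokes-Einstein", {
  sp <- std_species()
  co <- species_coefficients(sp, ctx)
  expect_rel_equal(co$s_s * co$f_g_s, sp$mb, 1e-12)
  expect_rel_equal(co$D_cm2_s * co$f_g_s,
                   physical_constants()$k_B * ctx$T, 1e-12)
})

test_that("single BD step has the specified displacement statistics", {
  ## frozen one-step values: r = 6 cm, s = 5e-13, omega = 5236, dt = 10 s
  omega <- 5236
  dr_sed <- 6 * expm1(5e-13 * omega^2 * 10)
  expect_rel_equal(dr_sed, 8.225e-4, 1e-3)
  expect_rel_equal(sqrt(2 * 4e-7 * 10), 2.828e-3, 1e-3)
})

test_that("BD with D = 0 reproduces the analytic boundary to machine precision", {
  run <- rotor_run(rpm = 50000, scan_times_s = c(1200, 2400, 3600))
  sp <- std_species()
  co <- species_coefficients(sp, ctx)
  bb <- bd_simulate(sp, run, geom, ctx, n_particles = 4000, dt = 10,
                    seed = 3, n_bins = 800, D_override = 0,
                    keep_trajectories = TRUE)
  ## every particle follows r0 * exp(s w^2 t) exactly: the trailing particle
  ## (the boundary) grows by the same factor as the analytic boundary
  r_bnd <- min(bb$trajectories[[1]])
  set.seed(3)
  r0_min <- min(sqrt(geom$r_m^2 + runif(4000) * (geom$r_b^2 - geom$r_m^2)))
  growth <- as.numeric(
    boundary_position_analytic(co$s_s, run, geom, 3600)) / geom$r_m
  expect_rel_equal(r_bnd, r0_min * growth, 1e-12)
  ## profile is a clean step: zero signal below the boundary
  last <- dplyr::filter(bb$scans, .data$time_s == 3600)
  expect_true(all(last$signal[last$radius_cm < r_bnd * 0.999] == 0))
})

test_that("BD with s = 0 is pure diffusion with variance 2 D k dt", {
  run <- rotor_run(rpm = 50000, scan_times_s = 200)
  ## zero buoyant mass: no drift
  sp <- sedimenting_species(RH_cm = 2e-7, mb_g = 0)
  D <- species_coefficients(sp, ctx)$D_cm2_s
  ## wide cell so boundaries are untouched
  wide <- cell_geometry(3, 12)
  bb <- bd_simulate(sp, run, wide, ctx, n_particles = 1e5, dt = 10,
                    seed = 5, keep_trajectories = TRUE)
  r_end <- bb$trajectories[[1]]
  ## compare against the same initial positions regenerated from the seed
  set.seed(5)
  r0 <- sqrt(wide$r_m^2 + runif(1e5) * (wide$r_b^2 - wide$r_m^2))
  disp <- r_end - r0
  expect_lt(abs(mean(disp)), 3 * sd(disp) / sqrt(length(disp)))
  v_expect <- 2 * D * 200
  se_var <- v_expect * sqrt(2 / (length(disp) - 1))
  expect_lt(abs(var(disp) - v_expect), 3 * se_var)
})

test_that("BD warns when the time step is too coarse", {
  run <- rotor_run(rpm = 50000, scan_times_s = 3600)
  fast <- sedimenting_species(RH_cm = 2e-7, mb_g = 2e-18)
  expect_warning(bd_simulate(fast, run, geom, ctx, n_particles = 10,
                             dt = 2000, seed = 1), "Time step")
})

test_that("Lamm solver conserves sector mass to 1e-6 and relaxes at s = 0", {
  run <- rotor_run(rpm = 50000, scan_times_s = seq(1200, 6000, by = 1200))
  ss <- lamm_solve(std_species(), run, geom, ctx, radial_points = 300)
  m <- sector_mass(ss)
  expect_lt(max(abs(m$mass / m$mass[1] - 1)), 1e-6)
  ## s = 0: pure diffusion relaxes toward uniform, mass conserved
  sp0 <- sedimenting_species(RH_cm = 2e-7, mb_g = 0, c0 = 1)
  run2 <- rotor_run(rpm = 50000, scan_times_s = c(500, 50000))
  ss0 <- lamm_solve(sp0, run2, geom, ctx, radial_points = 120)
  m0 <- sector_mass(ss0)
  expect_lt(max(abs(m0$mass / m0$mass[1] - 1)), 1e-9)
  final <- dplyr::filter(ss0$scans, .data$time_s == 50000)
  expect_lt(diff(range(final$signal)), 1e-3)
})

test_that("plateau dilution matches the characteristics solution exp(-2 w^2 s t)", {
  run <- rotor_run(rpm = 50000, scan_times_s = seq(1200, 4800, by = 1200))
  sp <- std_species()
  s <- species_coefficients(sp, ctx)$s_s
  ## small-D regime (D = 0 gives the exact characteristics solution)
  ss <- lamm_solve(sp, run, geom, ctx, radial_points = 300, D_override = 0)
  for (t in run$scan_times) {
    prof <- dplyr::filter(ss$scans, .data$time_s == t)
    mid <- dplyr::filter(prof, .data$radius_cm > 6.6, .data$radius_cm < 6.9)
    expect_rel_equal(median(mid$signal), exp(-2 * run$omega^2 * s * t),
                     5e-3)
  }
})

test_that("Lamm boundary midpoint tracks the analytic boundary within a cell", {
  run <- rotor_run(rpm = 50000, scan_times_s = seq(1200, 4800, by = 1200))
  sp <- std_species()
  s <- species_coefficients(sp, ctx)$s_s
  ss <- lamm_solve(sp, run, geom, ctx, radial_points = 300,
                   D_override = 2e-7, courant = 0.2)
  dr <- (geom$r_b - geom$r_m) / 300
  for (t in run$scan_times) {
    prof <- dplyr::filter(ss$scans, .data$time_s == t)
    plat <- median(prof$signal[prof$radius_cm > 6.7 & prof$radius_cm < 7.0])
    i <- which(prof$signal >= plat / 2)[1]
    r_mid <- prof$radius_cm[i]
    r_true <- as.numeric(boundary_position_analytic(s, run, geom, t))
    expect_lt(abs(r_mid - r_true), 2 * dr)
  }
})

test_that("increasing RH at fixed buoyant mass slows and sharpens the boundary", {
  run <- rotor_run(rpm = 50000, scan_times_s = 3000)
  mb <- 4e-20
  prof <- lapply(c(2e-7, 4e-7), function(RH) {
    ss <- lamm_solve(sedimenting_species(RH, mb), run, geom, ctx,
                     radial_points = 200)
    ss$scans
  })
  bnd <- vapply(prof, function(sc) {
    plat <- median(sc$signal[sc$radius_cm > 6.8])
    sc$radius_cm[which(sc$signal >= plat / 2)[1]]
  }, numeric(1))
  expect_gt(bnd[1], bnd[2])   # smaller RH -> larger s -> faster boundary
})

test_that("s is recovered from Lamm scans within 2% and from BD within 3 SE", {
  run <- rotor_run(rpm = 50000, scan_times_s = seq(1200, 6000, by = 1200))
  sp <- std_species()
  s_true <- species_coefficients(sp, ctx)$s_s
  ss <- lamm_solve(sp, run, geom, ctx, radial_points = 400)
  f1 <- fit_s_from_boundary(ss)
  expect_rel_equal(f1$s, s_true, 0.02)
  bb <- bd_simulate(sp, run, geom, ctx, n_particles = 1e5, dt = 10,
                    seed = 11)
  f2 <- fit_s_from_boundary(bb)
  expect_lt(abs(f2$s - s_true), 3 * max(f2$s_se, 0.01 * s_true))
  ## D = 0 synthetic step profiles recover s essentially exactly
  ss0 <- lamm_solve(sp, run, geom, ctx, radial_points = 600,
                    D_override = 0)
  f3 <- fit_s_from_boundary(ss0)
  expect_rel_equal(f3$s, s_true, 0.005)
})

test_that("fit_s_from_boundary raises a diagnostic without a boundary", {
  run <- rotor_run(rpm = 50000, scan_times_s = c(10, 20, 30))
  sp0 <- sedimenting_species(RH_cm = 2e-7, mb_g = 0)   # nothing sediments
  ss <- lamm_solve(sp0, run, geom, ctx, radial_points = 100)
  expect_error(fit_s_from_boundary(ss), "No detectable boundary")
})

test_that("BD converges to the Lamm solution as n grows (~ n^-1/2)", {
  run <- rotor_run(rpm = 50000, scan_times_s = c(1800, 3600))
  sp <- std_species()
  ref <- lamm_solve(sp, run, geom, ctx, radial_points = 200,
                    courant = 0.05)
  ## compare away from the bottom: the continuum solver accumulates mass
  ## in a thin layer at r_b while the particle simulator pellets it
  l2 <- vapply(c(1e3, 1e4, 1e5), function(n) {
    bb <- bd_simulate(sp, run, geom, ctx, n_particles = as.integer(n),
                      dt = 10, seed = 7, n_bins = 200)
    err <- 0
    for (t in run$scan_times) {
      b <- dplyr::filter(bb$scans, .data$time_s == t,
                         .data$radius_cm < geom$r_b - 0.15)
      r <- dplyr::filter(ref$scans, .data$time_s == t)
      zi <- approx(r$radius_cm, r$signal, xout = b$radius_cm, rule = 2)$y
      err <- err + mean((b$signal - zi)^2)
    }
    sqrt(err)
  }, numeric(1))
  expect_true(all(diff(l2) < 0))
  ## decade steps in n shrink the error roughly like sqrt(10)
  expect_gt(l2[1] / l2[2], 2.0)
  expect_gt(l2[2] / l2[3], 2.0)
  expect_lt(l2[1] / l2[2], 4.5)
  expect_lt(l2[2] / l2[3], 4.5)
})

test_that("D/ff0 conversion identities hold and invert exactly", {
  sol <- solute_spec(M = 5e4, vbar = 0.73)
  set.seed(9)
  for (k in 1:10) {
    s <- 10^runif(1, -13.5, -12)
    ff0 <- runif(1, 1, 2.5)
    D1 <- diffusion_from_s_ff0(s, ff0, sol, ctx, form = "kBT")
    D2 <- diffusion_from_s_ff0(s, ff0, sol, ctx, form = "RT")
    expect_rel_equal(D1, D2, 1e-12)
    expect_rel_equal(ff0_from_s_D(s, D1, sol, ctx), ff0, 1e-12)
  }
  ## sphere: f/f0 from the hydrated frictional ratio gives Stokes-Einstein D
  R <- volume_equivalent_radius(sol$M, sol$vbar)
  obs <- observables_from_radii(c(aT = R), ctx, sol)
  ff0_sphere <- frictional_ratio_hydrated(obs$f, sol, ctx)
  D_pred <- diffusion_from_s_ff0(obs$s, ff0_sphere, sol, ctx)
  expect_rel_equal(D_pred, obs$D, 1e-10)
  ## neutral buoyancy rejected
  expect_error(
    diffusion_from_s_ff0(5e-13, 1.2, solute_spec(5e4, 1 / ctx$rho), ctx),
    "buoyancy")
})
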