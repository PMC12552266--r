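## Forward models of sedimentation velocity in a sector-shaped cell:
## analytic no-diffusion boundary, Brownian-dynamics particle simulation,
## and a finite-volume Lamm-equation solver.

#' Centrifuge cell geometry
#'
#' @param meniscus_cm Meniscus radius \eqn{r_m} (cm, distance from the rotor
#'   axis).
#' @param bottom_cm Cell bottom radius \eqn{r_b} (cm); must exceed the
#'   meniscus.
#' @return An object of class `cell_geometry`.
#' @examples
#' cell_geometry(6.0, 7.2)
#' @export
cell_geometry <- function(meniscus_cm = 6.0, bottom_cm = 7.2) {
  stopifnot(is.numeric(meniscus_cm), is.numeric(bottom_cm))
  if (!(meniscus_cm > 0 && bottom_cm > meniscus_cm)) {
    abort("Need 0 < meniscus < bottom.")
  }
  structure(list(r_m = meniscus_cm, r_b = bottom_cm),
            class = "cell_geometry")
}

#' Rotor run: speed and scan schedule
#'
#' @param rpm Rotor speed in revolutions per minute (alternative to
#'   `omega`).
#' @param omega Angular velocity (rad/s).
#' @param scan_times_s Strictly increasing scan times (s), first >= 0.
#' @return An object of class `rotor_run` with `omega` and `scan_times`.
#' @examples
#' rotor_run(rpm = 50000, scan_times_s = seq(600, 3600, by = 600))
#' @export
rotor_run <- function(rpm = NULL, omega = NULL, scan_times_s) {
  if (is.null(omega)) {
    stopifnot(!is.null(rpm), rpm > 0)
    omega <- rpm * 2 * pi / 60
  }
  stopifnot(omega > 0, length(scan_times_s) >= 1,
            all(diff(scan_times_s) > 0), scan_times_s[1] >= 0)
  structure(list(omega = omega, scan_times = as.numeric(scan_times_s)),
            class = "rotor_run")
}

#' Sedimenting species in (R_H, buoyant mass) coordinates
#'
#' The time course of sedimentation of a non-interacting species is fully
#' determined by two molecular quantities: the hydrodynamic (Stokes) radius
#' \eqn{R_{H,f}} and the buoyant mass per particle
#' \eqn{m^{(b)} = m(1-\bar v\rho)}.  Given the solvent, the working
#' coefficients follow as \eqn{f = 6\pi\eta_0 R_H},
#' \eqn{s = m^{(b)}/f} and \eqn{D = k_B T/f}.
#'
#' @param RH_cm Hydrodynamic radius (cm).
#' @param mb_g Buoyant mass per particle (g).  The buoyant molar mass is
#'   \eqn{M^{(b)} = N_A m^{(b)}}.
#' @param c0 Initial (loading) signal concentration, arbitrary units >= 0.
#' @return An object of class `sed_species`.
#' @seealso [species_coefficients()] for s, D, f in a solvent.
#' @examples
#' sedimenting_species(RH_cm = 2e-7, mb_g = 2.25e-20)
#' @export
sedimenting_species <- function(RH_cm, mb_g, c0 = 1) {
  stopifnot(RH_cm > 0, c0 >= 0)
  structure(list(RH = RH_cm, mb = mb_g, c0 = c0), class = "sed_species")
}

#' Sedimentation, diffusion and friction coefficients of a species
#'
#' @param sp A [sedimenting_species()] or a list of them.
#' @param ctx A [solvent_context()].
#' @return A tibble with one row per species: `RH_cm`, `mb_g`, `c0`,
#'   `f_g_s`, `s_s`, `D_cm2_s`.
#' @export
species_coefficients <- function(sp, ctx) {
  ctx <- .as_ctx(ctx)
  sp <- .species_list(sp)
  purrr::map_dfr(sp, function(x) {
    f <- 6 * pi * ctx$eta0 * x$RH
    tibble::tibble(RH_cm = x$RH, mb_g = x$mb, c0 = x$c0,
                   f_g_s = f, s_s = x$mb / f, D_cm2_s = .kB * ctx$T / f)
  })
}

.species_list <- function(sp) {
  if (inherits(sp, "sed_species")) return(list(sp))
  if (is.list(sp) && all(vapply(sp, inherits, TRUE, "sed_species"))) {
    return(sp)
  }
  abort("`species` must be a sed_species or a list of them.")
}

#' Analytic boundary position without diffusion
#'
#' In the absence of diffusion every particle moves along
#' \eqn{\ln(r(t)/r_m) = \omega^2 s t}, so the step boundary sits at
#' \eqn{r = r_m e^{\omega^2 s t}}.  Positions beyond the cell bottom are
#' clipped to `r_b` and flagged via the `pelleted` attribute.
#'
#' @param s Sedimentation coefficient (s).
#' @param run A [rotor_run()] (its `omega` is used).
#' @param geometry A [cell_geometry()].
#' @param t Time(s) since the start of the run (s).
#' @return Boundary radius (cm), vectorised over `t`, with attribute
#'   `pelleted` (logical vector).
#' @export
boundary_position_analytic <- function(s, run, geometry, t) {
  stopifnot(all(t >= 0))
  r <- geometry$r_m * exp(run$omega^2 * s * t)
  pell <- r > geometry$r_b
  r[pell] <- geometry$r_b
  attr(r, "pelleted") <- pell
  r
}

## --- scan sets -----------------------------------------------------------

.new_scan_set <- function(scans, geometry, run, ctx, engine,
                          noise_sigma = 0, seed = NA_integer_,
                          extra = list()) {
  structure(c(list(scans = scans, geometry = geometry, run = run,
                   temperature_K = ctx$T, viscosity_poise = ctx$eta0,
                   engine = engine, noise_sigma = noise_sigma, seed = seed),
              extra),
            class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf(
    "<scan_set> %d scans x %d radii, engine = %s, cell %.3g-%.3g cm, %d rpm\n",
    length(unique(x$scans$scan_id)),
    length(unique(x$scans$radius_cm)), x$engine,
    x$geometry$r_m, x$geometry$r_b, round(x$run$omega * 60 / (2 * pi))))
  invisible(x)
}

#' @export
as_tibble.scan_set <- function(x, ...) x$scans

#' Brownian-dynamics simulation of sedimentation velocity
#'
#' Simulates individual particle trajectories in the centrifugal field: per
#' time step the radial position advances by the deterministic displacement
#' \eqn{\Delta r_{sed} = r\,(e^{s\omega^2\Delta t} - 1)} plus a Gaussian
#' Brownian displacement of zero mean and variance \eqn{2D\Delta t}.
#' Particles reflect at the meniscus and are absorbed into a pellet at the
#' bottom (excluded from the profiles, so cell mass bookkeeping is exact).
#' Initial positions are distributed proportional to r (uniform
#' concentration in a sector cell) and concentration profiles are estimated
#' as bin count/(r dr), again per sector geometry.
#'
#' @param species A [sedimenting_species()] or list of them.
#' @param run A [rotor_run()].
#' @param geometry A [cell_geometry()].
#' @param ctx A [solvent_context()].
#' @param n_particles Particles per species.
#' @param dt Time step (s).  A warning is issued when
#'   \eqn{e^{s\omega^2 dt} - 1 > 0.01} (single-step displacement formula
#'   validity).
#' @param seed Integer seed; recorded in the result.
#' @param n_bins Radial bins for the concentration estimate.
#' @param keep_trajectories If TRUE, the final particle radii are attached.
#' @param D_override Optional diffusion coefficient (cm^2/s) imposed on all
#'   species in place of the Stokes--Einstein value; `0` gives the
#'   deterministic no-diffusion limit.
#' @return A `scan_set` whose signal is the binned concentration, plus a
#'   `pelleted_fraction` field per scan.
#' @export
bd_simulate <- function(species, run, geometry, ctx,
                        n_particles = 10000L, dt = 10, seed = 1L,
                        n_bins = 200L, keep_trajectories = FALSE,
                        D_override = NULL) {
  ctx <- .as_ctx(ctx)
  coefs <- species_coefficients(species, ctx)
  if (!is.null(D_override)) coefs$D_cm2_s <- D_override
  stopifnot(dt > 0, n_particles >= 1)
  if (any(expm1(coefs$s_s * run$omega^2 * dt) > 0.01)) {
    warn(paste0("Time step too coarse: exp(s*omega^2*dt) - 1 > 0.01; ",
                "single-step sedimentation displacement may be inaccurate."))
  }
  set.seed(seed)
  r_m <- geometry$r_m; r_b <- geometry$r_b
  edges <- seq(r_m, r_b, length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  dr <- diff(edges)[1]
  all_scans <- list(); pellet <- numeric(0); traj <- list()
  for (k in seq_len(nrow(coefs))) {
    s <- coefs$s_s[k]; D <- coefs$D_cm2_s[k]; c0 <- coefs$c0[k]
    ## sector-weighted uniform start: density prop. to r
    u <- runif(n_particles)
    r <- sqrt(r_m^2 + u * (r_b^2 - r_m^2))
    alive <- rep(TRUE, n_particles)
    grow <- exp(s * run$omega^2 * dt)
    sdB <- sqrt(2 * D * dt)
    t_now <- 0
    w <- c0 * (r_b^2 - r_m^2) / (2 * n_particles)  # signal weight/particle
    for (it in seq_along(run$scan_times)) {
      t_target <- run$scan_times[it]
      while (t_now < t_target - 1e-9) {
        step <- min(dt, t_target - t_now)
        g <- if (step == dt) grow else exp(s * run$omega^2 * step)
        sB <- if (step == dt) sdB else sqrt(2 * D * step)
        idx <- which(alive)
        rn <- r[idx] * g + rnorm(length(idx), sd = sB)
        ## reflect at meniscus, absorb at bottom
        rn <- ifelse(rn < r_m, 2 * r_m - rn, rn)
        rn <- ifelse(rn < r_m, r_m, rn)   # double reflection guard
        dead <- rn >= r_b
        alive[idx[dead]] <- FALSE
        r[idx] <- ifelse(dead, r_b, rn)
        t_now <- t_now + step
      }
      counts <- tabulate(
        findInterval(r[alive], edges, rightmost.closed = TRUE),
        nbins = n_bins)
      conc <- counts * w / (mids * dr)
      all_scans[[length(all_scans) + 1]] <- tibble::tibble(
        scan_id = it, time_s = t_target, radius_cm = mids,
        signal = conc, species = k)
      pellet[(k - 1) * length(run$scan_times) + it] <-
        mean(!alive)
    }
    if (keep_trajectories) traj[[k]] <- r
  }
  scans <- dplyr::bind_rows(all_scans) |>
    dplyr::group_by(.data$scan_id, .data$time_s, .data$radius_cm) |>
    dplyr::summarise(signal = sum(.data$signal), .groups = "drop") |>
    dplyr::arrange(.data$time_s, .data$radius_cm)
  out <- .new_scan_set(scans, geometry, run, ctx, "bd", seed = seed,
                       extra = list(
                         n_particles = n_particles, dt = dt,
                         pelleted_fraction = pellet,
                         species = coefs))
  if (keep_trajectories) out$trajectories <- traj
  out
}

## --- Lamm equation solver ------------------------------------------------

## Finite-volume discretisation of the Lamm equation in conservative form,
##   dc/dt = (1/r) d/dr [ r ( D dc/dr - s w^2 r c ) ],
## on a uniform radial grid with zero-flux ends.  Face fluxes use
## exponential (Scharfetter-Gummel) fitting of the advection-diffusion
## flux, which yields an M-matrix: the implicit update is positivity
## preserving and conserves the sector mass integral c r dr to round-off.
.lamm_operator <- function(r, dr, D, sw2) {
  n <- length(r)
  faces <- (r[-n] + r[-1]) / 2
  v <- sw2 * faces                       # advection velocity at faces
  if (D > 0) {
    pe <- v * dr / D                     # face Peclet numbers
    bern <- function(x) ifelse(abs(x) < 1e-10, 1 - x / 2,
                               x / expm1(x))
    ## flux_f = (D/dr) * [ B(-pe) c_left - B(pe) c_right ] * r_f
    aL <- (D / dr) * bern(-pe) * faces
    aR <- (D / dr) * bern(pe) * faces
  } else {
    ## pure advection: upwind flux, flux_f = v r_f c_upwind
    aL <- ifelse(v > 0, v * faces, 0)
    aR <- ifelse(v < 0, -v * faces, 0)
  }
  ## dc_i/dt = (flux_in - flux_out)/(r_i dr)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1) {   # inflow face i-1/2
      L[i, i - 1] <- L[i, i - 1] + aL[i - 1] / (r[i] * dr)
      L[i, i]     <- L[i, i]     - aR[i - 1] / (r[i] * dr)
    }
    if (i < n) {   # outflow face i+1/2
      L[i, i]     <- L[i, i]     - aL[i] / (r[i] * dr)
      L[i, i + 1] <- L[i, i + 1] + aR[i] / (r[i] * dr)
    }
  }
  L
}

#' Numerical solution of the Lamm equation
#'
#' Solves the sedimentation--diffusion transport equation
#' \deqn{\frac{\partial c}{\partial t} =
#'   D\left[\frac{\partial^2 c}{\partial r^2} +
#'   \frac1r \frac{\partial c}{\partial r}\right]
#'   - s\omega^2\left[r\frac{\partial c}{\partial r} + 2c\right]}
#' in a sector-shaped cell with zero-flux conditions at meniscus and bottom
#' and uniform initial concentration `c0`, by an implicit exponentially
#' fitted finite-volume scheme in conservative form (see the methods
#' vignette).  Multiple species superpose (non-interacting).  The
#' sector mass \eqn{\int c\, r\, dr} is conserved to round-off; the solver
#' aborts if the solution develops negative concentrations beyond
#' \eqn{-10^{-9} c_0} or the mass drifts by more than \eqn{10^{-4}}
#' relative.
#'
#' @inheritParams bd_simulate
#' @param radial_points Number of radial cells (>= 50; default 400).
#' @param dt Optional time step (s); by default chosen so that the advective
#'   Courant number \eqn{s\omega^2 r_b \Delta t/\Delta r} is at most 0.5.
#' @param D_override Optional diffusion coefficient (cm^2/s) imposed on all
#'   species; `0` gives the pure-advection (characteristics) limit.
#' @param courant Advective Courant target used to pick the default time
#'   step (default 0.5).  The implicit scheme is stable at any value; a
#'   smaller target reduces the first-order temporal error (numerical
#'   boundary broadening of order \eqn{v^2 \Delta t/2}).
#' @return A `scan_set` with the concentration profiles at the scan times.
#' @export
lamm_solve <- function(species, run, geometry, ctx,
                       radial_points = 400L, dt = NULL, D_override = NULL,
                       courant = 0.5) {
  ctx <- .as_ctx(ctx)
  coefs <- species_coefficients(species, ctx)
  if (!is.null(D_override)) coefs$D_cm2_s <- D_override
  stopifnot(radial_points >= 50)
  n <- radial_points
  r_m <- geometry$r_m; r_b <- geometry$r_b
  edges <- seq(r_m, r_b, length.out = n + 1)
  r <- (edges[-1] + edges[-(n + 1)]) / 2
  dr <- diff(edges)[1]
  times <- run$scan_times
  total <- matrix(0, length(times), n)
  for (k in seq_len(nrow(coefs))) {
    s <- coefs$s_s[k]; D <- coefs$D_cm2_s[k]; c0 <- coefs$c0[k]
    if (c0 == 0) next
    sw2 <- s * run$omega^2
    dt_cfl <- courant * dr / max(abs(sw2) * r_b, 1e-30)
    dt_k <- min(dt %||% dt_cfl, dt_cfl, max(diff(c(0, times))))
    L <- .lamm_operator(r, dr, D, sw2)
    A <- diag(n) - dt_k * L              # implicit step matrix
    Ainv <- solve(A)
    cvec <- rep(c0, n)
    mass0 <- sum(cvec * r) * dr
    t_now <- 0
    for (it in seq_along(times)) {
      t_target <- times[it]
      while (t_now < t_target - 1e-9) {
        step <- min(dt_k, t_target - t_now)
        if (abs(step - dt_k) < 1e-12) {
          cvec <- Ainv %*% cvec
        } else {
          cvec <- solve(diag(n) - step * L, cvec)
        }
        t_now <- t_now + step
      }
      cvec <- as.numeric(cvec)
      if (any(cvec < -1e-9 * c0)) {
        abort(sprintf(
          "Lamm solver instability: negative concentration at dt = %g s.",
          dt_k))
      }
      mass <- sum(cvec * r) * dr
      if (abs(mass / mass0 - 1) > 1e-4) {
        abort(sprintf(
          "Lamm solver mass drift %.2e at dt = %g s.",
          abs(mass / mass0 - 1), dt_k))
      }
      total[it, ] <- total[it, ] + cvec
    }
  }
  scans <- purrr::map_dfr(seq_along(times), function(it) {
    tibble::tibble(scan_id = it, time_s = times[it], radius_cm = r,
                   signal = total[it, ])
  })
  .new_scan_set(scans, geometry, run, ctx, "lamm",
                extra = list(radial_points = n, species = coefs))
}

#' Sector mass of a scan set
#'
#' The sector-weighted integral \eqn{\int c\, r\, dr} per scan (trapezoid on
#' the radial grid), the conserved quantity of the transport equation until
#' material pellets at the bottom.
#'
#' @param ss A `scan_set`.
#' @return Tibble with `scan_id`, `time_s`, `mass`.
#' @export
sector_mass <- function(ss) {
  ss$scans |>
    dplyr::group_by(.data$scan_id, .data$time_s) |>
    dplyr::summarise(
      mass = {
        ## rectangle rule on the uniform cell-centre grid: this is the
        ## discrete invariant of the finite-volume operator
        r <- .data$radius_cm; z <- .data$signal
        sum(z * r) * mean(diff(r))
      },
      .groups = "drop")
}

#' Sedimentation coefficient from boundary midpoint motion
#'
#' Locates the boundary in each scan as the radius where the signal crosses
#' the mid-level between the solvent plateau (near the meniscus) and the
#' solution plateau (ahead of the boundary), by monotone interpolation, then
#' fits \eqn{\ln(r/r_m)} against time; the slope is \eqn{\omega^2 s}.
#'
#' @param ss A `scan_set`.
#' @param method Boundary locator; only `"midpoint"` is implemented.
#' @param plateau_frac Fraction of the column (adjacent to each end) used to
#'   estimate the plateaus (default 0.15); the bottom 10% of the column is
#'   excluded from the solution-plateau estimate to avoid bottom pile-up.
#' @return A one-row tibble: `s` (s), `s_se` (standard error), `n_scans`.
#' @export
fit_s_from_boundary <- function(ss, method = c("midpoint"),
                                plateau_frac = 0.15) {
  method <- match.arg(method)
  r_m <- ss$geometry$r_m; r_b <- ss$geometry$r_b
  rows <- ss$scans |>
    dplyr::group_by(.data$scan_id, .data$time_s) |>
    dplyr::group_map(function(tbl, key) {
      r <- tbl$radius_cm; z <- tbl$signal
      n <- length(r)
      if (n < 20) return(NULL)
      ## locate the boundary as the steepest rise (lightly smoothed),
      ## restricted to the inner 90% of the column
      g <- diff(z)
      k <- min(5, max(1, floor(n / 40)))
      gs <- stats::filter(g, rep(1 / k, k), sides = 2)
      gs[is.na(gs)] <- 0
      hi_end <- floor(0.9 * n)
      i_bnd <- which.max(gs[seq_len(hi_end)])
      if (gs[i_bnd] <= 0) return(NULL)
      ## extent of the rising region around the boundary
      ups <- which(gs > 0.1 * gs[i_bnd])
      cand <- ups[ups >= i_bnd & ups <= hi_end]
      if (length(cand) == 0) cand <- i_bnd
      brk <- which(diff(cand) > 1)
      i_up_end <- if (length(brk) == 0) max(cand) else cand[brk[1]]
      ## solution plateau: past the boundary, clear of the bottom
      i_hi <- seq(min(i_up_end + 3, hi_end), hi_end)
      if (length(i_hi) < 5) return(NULL)   # boundary too close to bottom
      plat_hi <- median(z[i_hi])
      ## solvent plateau: first points past the meniscus
      i_lo <- seq_len(max(3, floor(plateau_frac * n / 3)))
      plat_lo <- median(z[i_lo])
      if (!is.finite(plat_hi) || plat_hi <= 0) return(NULL)
      ## boundary must have cleared the meniscus
      if (plat_lo > 0.35 * plat_hi) return(NULL)
      mid <- (plat_lo + plat_hi) / 2
      above <- which(z >= mid)
      above <- above[above > 1 & above <= hi_end]
      if (length(above) == 0) return(NULL)
      i2 <- above[1]
      i1 <- i2 - 1
      if (z[i2] == z[i1]) return(NULL)
      r_mid <- r[i1] + (mid - z[i1]) / (z[i2] - z[i1]) * (r[i2] - r[i1])
      if (r_mid <= r_m || r_mid >= r_b) return(NULL)
      tibble::tibble(time_s = key$time_s, r_mid = r_mid)
    }) |>
    dplyr::bind_rows()
  if (nrow(rows) < 3) {
    abort(paste0("No detectable boundary in at least 3 scans (pelleted, ",
                 "not yet cleared from the meniscus, or too noisy)."))
  }
  fit <- lm(log(r_mid / r_m) ~ time_s, data = rows)
  slope <- coef(fit)[["time_s"]]
  se <- summary(fit)$coefficients["time_s", "Std. Error"]
  tibble::tibble(s = slope / ss$run$omega^2,
                 s_se = se / ss$run$omega^2,
                 n_scans = nrow(rows))
}

## --- f/f0 - D conversion identities -------------------------------------

#' Diffusion coefficient from s and the frictional ratio
#'
#' The identity used by Lamm-equation analysis software to supply D given s
#' and an assumed frictional ratio:
#' \deqn{D = \frac{\sqrt 2}{18\pi} k_B T\, s^{-1/2}
#'   \left[\eta_0 (f/f_0)\right]^{-3/2}
#'   \left(\frac{1-\bar v\rho}{\bar v}\right)^{1/2}.}
#' Both published algebraic arrangements (the \eqn{k_BT} form and the
#' \eqn{RT/N_A} form) are implemented and agree identically since
#' \eqn{R = k_B N_A}.
#'
#' @param s Sedimentation coefficient (s), > 0.
#' @param ff0 Frictional ratio (dimensionless, >= 1 physically).
#' @param solute A [solute_spec()] (vbar used).
#' @param ctx A [solvent_context()].
#' @param form `"kBT"` or `"RT"` — the two equivalent arrangements.
#' @return Diffusion coefficient (cm^2/s).
#' @export
diffusion_from_s_ff0 <- function(s, ff0, solute, ctx,
                                 form = c("kBT", "RT")) {
  form <- match.arg(form)
  ctx <- .as_ctx(ctx); solute <- .as_solute(solute)
  stopifnot(s > 0, ff0 > 0)
  b <- .buoyancy(solute, ctx, require_positive = TRUE)
  if (form == "kBT") {
    sqrt(2) / (18 * pi) * .kB * ctx$T / sqrt(s) *
      (ctx$eta0 * ff0)^(-3 / 2) * sqrt(b / solute$vbar)
  } else {
    .Rgas * ctx$T /
      (.NA * 18 * pi * (ctx$eta0 * ff0)^(3 / 2) *
         sqrt(s * solute$vbar / (2 * b)))
  }
}

#' Frictional ratio from s and D
#'
#' Exact inverse of [diffusion_from_s_ff0()]:
#' \deqn{f/f_0 = \left(\frac{\sqrt2}{18\pi}\right)^{2/3}
#'   \left(\frac{k_B T}{D}\right)^{2/3} \frac{s^{-1/3}}{\eta_0}
#'   \left(\frac{1-\bar v\rho}{\bar v}\right)^{1/3}.}
#'
#' @param s Sedimentation coefficient (s), > 0.
#' @param D Diffusion coefficient (cm^2/s), > 0.
#' @inheritParams diffusion_from_s_ff0
#' @return Frictional ratio (dimensionless).
#' @export
ff0_from_s_D <- function(s, D, solute, ctx) {
  ctx <- .as_ctx(ctx); solute <- .as_solute(solute)
  stopifnot(s > 0, D > 0)
  b <- .buoyancy(solute, ctx, require_positive = TRUE)
  (sqrt(2) / (18 * pi))^(2 / 3) * (.kB * ctx$T / D)^(2 / 3) *
    s^(-1 / 3) / ctx$eta0 * (b / solute$vbar)^(1 / 3)
}
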