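## Equivalent radii: a_T (translational), a_I (viscometric), a_G (gyration),
## a_V (volume).  Each is the radius of the sphere sharing the corresponding
## property with the particle.  All radii in cm, all inputs CGS.

#' Translational equivalent (Stokes) radius
#'
#' The radius of the sphere with the same friction coefficient as the
#' particle, \eqn{a_T = f/(6\pi\eta_0)}.  Exactly one source must be given:
#' the friction coefficient `f` directly, the diffusion coefficient `D`
#' (Stokes--Einstein, requires `ctx`), or the sedimentation coefficient `s`
#' (requires `ctx` and `solute` for the buoyant mass).  This is the
#' hydrodynamic radius \eqn{R_{H,f}} reported by DLS instruments and by
#' hydrodynamic model calculations.
#'
#' @param f Friction coefficient (g/s).
#' @param D Translational diffusion coefficient (cm^2/s).
#' @param s Sedimentation coefficient (s); needs `solute` for M and vbar.
#' @param ctx A [solvent_context()].
#' @param solute A [solute_spec()] (s-form only).
#' @return Radius in cm.
#' @examples
#' ctx <- solvent_context(293.15, 0.01002, 0.998)
#' translational_radius(D = 2.1429e-6, ctx = ctx)   # ~1e-7 cm
#' @export
translational_radius <- function(f = NULL, D = NULL, s = NULL,
                                 ctx = NULL, solute = NULL) {
  n_src <- sum(!is.null(f), !is.null(D), !is.null(s))
  if (n_src != 1) {
    abort("Supply exactly one of `f`, `D` or `s` to translational_radius().")
  }
  if (!is.null(f)) {
    stopifnot(all(f > 0))
    eta0 <- if (is.null(ctx)) 1 else .as_ctx(ctx)$eta0
    if (is.null(ctx)) {
      abort("The f-form needs `ctx` for the solvent viscosity.")
    }
    return(f / (6 * pi * eta0))
  }
  if (!is.null(D)) {
    stopifnot(all(D > 0))
    ctx <- .as_ctx(ctx)
    return(.kB * ctx$T / (6 * pi * ctx$eta0 * D))
  }
  ctx <- .as_ctx(ctx); solute <- .as_solute(solute)
  b <- .buoyancy(solute, ctx)
  solute$M * b / (6 * pi * ctx$eta0 * .NA * s)
}

#' Viscometric equivalent radius
#'
#' The radius of the sphere with the same intrinsic viscosity and molecular
#' weight as the particle, \eqn{a_I = (3 M [\eta] / (10 \pi N_A))^{1/3}}.
#' Also known as the viscosity hydrodynamic radius \eqn{R_{H,\eta}}.
#'
#' @param eta_intr Intrinsic viscosity (cm^3/g).
#' @param M Molecular weight (Da).
#' @return Radius in cm.
#' @seealso [intrinsic_viscosity()] for the inverse map.
#' @export
viscometric_radius <- function(eta_intr, M) {
  stopifnot(all(eta_intr > 0), all(M > 0))
  (3 * M * eta_intr / (10 * pi * .NA))^(1 / 3)
}

#' Intrinsic viscosity of the equivalent sphere
#'
#' Inverse of [viscometric_radius()]: \eqn{[\eta] = 10\pi N_A a_I^3/(3M)}.
#'
#' @param a_I Viscometric equivalent radius (cm).
#' @param M Molecular weight (Da).
#' @return Intrinsic viscosity in cm^3/g.
#' @export
intrinsic_viscosity <- function(a_I, M) {
  stopifnot(all(a_I > 0), all(M > 0))
  10 * pi * .NA * a_I^3 / (3 * M)
}

#' Gyration equivalent radius
#'
#' The radius of the solid sphere with the same radius of gyration,
#' \eqn{a_G = \sqrt{5/3}\, R_g \approx 1.291\, R_g}.
#'
#' @param Rg Radius of gyration (cm).
#' @return Radius in cm.
#' @export
gyration_equivalent_radius <- function(Rg) {
  stopifnot(all(Rg > 0))
  sqrt(5 / 3) * Rg
}

#' Volume equivalent radius
#'
#' The radius of the sphere with the same anhydrous volume as the particle,
#' \eqn{a_V = (3 M \bar v/(4 \pi N_A))^{1/3}}.
#'
#' @param M Molecular weight (Da).
#' @param vbar Partial specific volume (cm^3/g).
#' @return Radius in cm.
#' @export
volume_equivalent_radius <- function(M, vbar) {
  stopifnot(all(M > 0), all(vbar > 0))
  (3 * M * vbar / (4 * pi * .NA))^(1 / 3)
}

#' Equivalent radii from a table of measured properties
#'
#' Converts a long-format property table into per-species equivalent radii.
#' The table must have columns `species`, `property`, `value` and optionally
#' `unit` and `sigma` (standard uncertainty).  Recognised properties are
#' `D` (cm^2/s), `s` (s or S), `f` (g/s), `eta_intr` (cm^3/g or dL/g),
#' `Rg` (cm or nm), plus the covariates `M` (Da) and `vbar` (cm^3/g).
#'
#' Radii are sparse: each is computed only when its sources are present, and
#' a `provenance` column records which measurement produced it.  When both
#' `D` and `s` are present, `a_T` is taken from `D` (direct, no buoyancy
#' needed) and the s-derived value is reported in its own row.  Per-property
#' uncertainties are propagated to first order (delta method).
#'
#' @param props Tibble/data.frame in long property format.
#' @param ctx A [solvent_context()].
#' @return A tibble with columns `species`, `radius` (one of aT, aI, aG, aV),
#'   `value` (cm), `sigma` (cm or NA) and `provenance`.
#' @examples
#' ctx <- solvent_context()
#' props <- tibble::tibble(
#'   species = "lysozyme",
#'   property = c("D", "M", "vbar"),
#'   value = c(1.06e-6, 14300, 0.703))
#' equivalent_radii(props, ctx)
#' @export
equivalent_radii <- function(props, ctx) {
  ctx <- .as_ctx(ctx)
  props <- .normalize_props(props)
  known <- c("D", "s", "f", "eta_intr", "Rg", "M", "vbar", "delta")
  bad <- setdiff(unique(props$property), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown property name(s): %s.", paste(bad, collapse = ", ")))
  }
  out <- props |>
    dplyr::group_by(.data$species) |>
    dplyr::group_map(function(tbl, key) {
      g <- function(p) tbl$value[match(p, tbl$property)]
      gs <- function(p) tbl$sigma[match(p, tbl$property)]
      rows <- list()
      add <- function(radius, value, sigma, prov) {
        rows[[length(rows) + 1]] <<- tibble::tibble(
          species = key$species, radius = radius, value = value,
          sigma = sigma, provenance = prov)
      }
      M <- g("M"); vbar <- g("vbar")
      if (!is.na(g("D"))) {
        aT <- translational_radius(D = g("D"), ctx = ctx)
        add("aT", aT, aT * .reldiv(gs("D"), g("D")), "measured-from-D")
      } else if (!is.na(g("f"))) {
        aT <- g("f") / (6 * pi * ctx$eta0)
        add("aT", aT, .reldiv(gs("f"), g("f")) * aT, "measured-from-f")
      } else if (!is.na(g("s")) && !is.na(M) && !is.na(vbar)) {
        sol <- solute_spec(M, vbar)
        aT <- translational_radius(s = g("s"), ctx = ctx, solute = sol)
        add("aT", aT, aT * .reldiv(gs("s"), g("s")), "measured-from-s")
      }
      if (!is.na(g("eta_intr")) && !is.na(M)) {
        aI <- viscometric_radius(g("eta_intr"), M)
        add("aI", aI, aI * .reldiv(gs("eta_intr"), g("eta_intr")) / 3,
            "measured-from-eta")
      }
      if (!is.na(g("Rg"))) {
        aG <- gyration_equivalent_radius(g("Rg"))
        add("aG", aG, sqrt(5 / 3) * gs("Rg"), "measured-from-Rg")
      }
      if (!is.na(M) && !is.na(vbar)) {
        add("aV", volume_equivalent_radius(M, vbar), NA_real_, "from-M-vbar")
      }
      dplyr::bind_rows(rows)
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    abort("No equivalent radius could be computed from the supplied table.")
  }
  out
}

.reldiv <- function(sig, val) {
  if (is.null(sig) || length(sig) == 0 || is.na(sig)) return(NA_real_)
  sig / val
}

.normalize_props <- function(props) {
  props <- tibble::as_tibble(props)
  need <- c("species", "property", "value")
  if (!all(need %in% names(props))) {
    abort("Property table needs columns species, property, value.")
  }
  if (!"sigma" %in% names(props)) props$sigma <- NA_real_
  if (!"unit" %in% names(props)) props$unit <- NA_character_
  ## convert user-facing units to CGS
  cgs_of <- c(D = NA, s = "s", f = NA, eta_intr = "cm3_per_g", Rg = "cm",
              M = "Da", vbar = "cm3_per_g", delta = NA)
  conv <- function(value, property, unit) {
    if (is.na(unit) || unit == "") return(value)
    target <- cgs_of[[property]]
    if (is.na(target)) {
      if (unit %in% c("cm2_per_s", "g_per_s", "1")) return(value)
      abort(sprintf("Unit '%s' not supported for property '%s'.",
                    unit, property))
    }
    convert_units(value, unit, target)
  }
  props$value <- purrr::pmap_dbl(
    list(props$value, props$property, props$unit), conv)
  props$sigma <- purrr::pmap_dbl(
    list(props$sigma, props$property, props$unit),
    function(v, p, u) if (is.na(v)) NA_real_ else conv(v, p, u))
  props
}

#' Ratios of equivalent radii
#'
#' Dimensionless shape/conformation indicators \eqn{XY = a_X/a_Y}: `IT`, `GT`,
#' `GI`, `TV`, `IV`.  Every ratio equals 1 for a sphere, and any ratio can be
#' combined from two others (XY = XZ/YZ), so `IT * GI == GT` whenever all
#' three are defined.
#'
#' @param radii Either a named numeric vector/list with entries among
#'   `aT`, `aI`, `aG`, `aV`, or a long tibble as returned by
#'   [equivalent_radii()] (per species).
#' @return A tibble with one row per species (a single unnamed row for the
#'   vector form) and columns among `IT`, `GT`, `GI`, `TV`, `IV`.
#' @examples
#' radii_ratios(c(aT = 1e-7, aI = 1.05e-7, aG = 1.6e-7))
#' @export
radii_ratios <- function(radii) {
  if (is.data.frame(radii)) {
    return(radii |>
             dplyr::group_by(.data$species) |>
             dplyr::group_map(function(tbl, key) {
               v <- setNames(tbl$value, tbl$radius)
               dplyr::bind_cols(tibble::tibble(species = key$species),
                                .ratios_one(v))
             }) |>
             dplyr::bind_rows())
  }
  .ratios_one(unlist(radii))
}

.ratios_one <- function(v) {
  pick <- function(n) if (n %in% names(v)) unname(v[[n]]) else NA_real_
  aT <- pick("aT"); aI <- pick("aI"); aG <- pick("aG"); aV <- pick("aV")
  if (sum(!is.na(c(aT, aI, aG, aV))) < 2) {
    abort("At least two equivalent radii are needed to form ratios.")
  }
  tibble::tibble(IT = aI / aT, GT = aG / aT, GI = aG / aI,
                 TV = aT / aV, IV = aI / aV)
}

#' Measurable properties from equivalent radii
#'
#' The inverse of the measurement-to-radius maps: given radii (and the
#' solvent/solute context) compute `f`, `D`, `s`, `eta_intr` and `Rg`.
#' Properties whose source radius is absent are returned as `NA`, not an
#' error.  A negative buoyancy factor propagates into a negative `s`
#' (flotation).
#'
#' @param radii Named vector/list with entries among `aT`, `aI`, `aG` (cm).
#' @param ctx A [solvent_context()].
#' @param solute A [solute_spec()]; needed for `s` (buoyancy) and
#'   `eta_intr` (mass).
#' @return A one-row tibble with columns `f`, `D`, `s`, `eta_intr`, `Rg`.
#' @export
observables_from_radii <- function(radii, ctx, solute = NULL) {
  ctx <- .as_ctx(ctx)
  v <- unlist(radii)
  pick <- function(n) if (n %in% names(v)) unname(v[[n]]) else NA_real_
  aT <- pick("aT"); aI <- pick("aI"); aG <- pick("aG")
  f <- if (!is.na(aT)) 6 * pi * ctx$eta0 * aT else NA_real_
  D <- if (!is.na(aT)) .kB * ctx$T / f else NA_real_
  s <- NA_real_
  eta <- NA_real_
  if (!is.null(solute)) {
    solute <- .as_solute(solute)
    if (!is.na(aT)) {
      s <- solute$M * (1 - solute$vbar * ctx$rho) / (.NA * f)
    }
    if (!is.na(aI)) eta <- intrinsic_viscosity(aI, solute$M)
  }
  Rg <- if (!is.na(aG)) aG / sqrt(5 / 3) else NA_real_
  tibble::tibble(f = f, D = D, s = s, eta_intr = eta, Rg = Rg)
}

## --- universal parameters ------------------------------------------------

## Coefficients of the ratio formulas, derived from the defining equations
## and the CODATA constants:
##   P0  = sqrt(10) pi / GT
##   Phi = 10 pi N_A / (3 (18/5)^(3/2)) / GI^3
##   beta = (pi N_A / 30)^(1/3) / (6 pi) * IT   (dL/g convention)
.P0_coef <- sqrt(10) * pi
.Phi_coef <- 10 * pi * .NA / (3 * (18 / 5)^(3 / 2))
.beta_coef <- (pi * .NA / 30)^(1 / 3) / (6 * pi)

#' Universal size/shape parameters
#'
#' Evaluates the classical dimension-combining parameters: the Flory
#' translational parameter \eqn{P_0}, the Flory viscosity parameter
#' \eqn{\Phi}, the Scheraga--Mandelkern parameter \eqn{\beta}, the Tsvetkov
#' hydrodynamic invariant \eqn{A_0 = k_B \beta}, and the intrinsic diffusion
#' and sedimentation coefficients \eqn{[D] = D\eta_0/T} and
#' \eqn{[s] = s\eta_0/(1 - \bar v \rho)}.
#'
#' Two input routes are supported and agree to better than 1e-10 relative
#' when both are possible: raw measured properties (`props` +
#' `solute` + `ctx`), or ratios of radii (`ratios`), using
#' \eqn{P_0 = \sqrt{10}\pi/GT}, \eqn{\Phi = 9.23\times 10^{23}/GI^3} and
#' \eqn{\beta = 2.112\times 10^6\, IT}.  Following the classical convention,
#' \eqn{\beta} and \eqn{A_0} use the dL/g unit for the intrinsic viscosity
#' internally (the \eqn{100^{-1/3}} factor); every other operation in the
#' package uses cm^3/g.
#'
#' @param props Optional named list/vector of raw properties among `f`, `D`,
#'   `s`, `eta_intr` (cm^3/g), `Rg` (cm).
#' @param solute,ctx [solute_spec()] and [solvent_context()] for the raw
#'   route.
#' @param ratios Optional named list/vector with entries among `IT`, `GT`,
#'   `GI` (or a one-row tibble from [radii_ratios()]).
#' @return One-row tibble with columns `P0`, `Phi`, `beta`, `A0`,
#'   `intrinsic_D`, `intrinsic_s` (NA where not computable).
#' @examples
#' universal_parameters(ratios = c(IT = 1, GT = 1, GI = 1))  # sphere values
#' @export
universal_parameters <- function(props = NULL, solute = NULL, ctx = NULL,
                                 ratios = NULL) {
  P0 <- Phi <- beta <- A0 <- iD <- is_ <- NA_real_
  if (!is.null(ratios)) {
    if (is.data.frame(ratios)) ratios <- as.list(ratios[1, ])
    r <- unlist(ratios)
    pick <- function(n) if (n %in% names(r)) unname(r[[n]]) else NA_real_
    GT <- pick("GT"); GI <- pick("GI"); IT <- pick("IT")
    if (is.na(IT) && !is.na(GT) && !is.na(GI)) IT <- GT / GI
    if (!is.na(GT)) P0 <- .P0_coef / GT
    if (!is.na(GI)) Phi <- .Phi_coef / GI^3
    if (!is.na(IT)) beta <- .beta_coef * IT
    if (is.na(beta) && !is.na(P0) && !is.na(Phi)) {
      beta <- Phi^(1 / 3) / (100^(1 / 3) * P0)
    }
  }
  if (!is.null(props)) {
    ctx <- .as_ctx(ctx)
    v <- unlist(props)
    pick <- function(n) if (n %in% names(v)) unname(v[[n]]) else NA_real_
    f <- pick("f"); D <- pick("D"); s <- pick("s")
    eta <- pick("eta_intr"); Rg <- pick("Rg")
    if (is.na(f) && !is.na(D)) f <- .kB * ctx$T / D
    if (!is.na(f) && !is.na(Rg)) P0 <- f / (sqrt(6) * ctx$eta0 * Rg)
    if (!is.null(solute)) {
      solute <- .as_solute(solute)
      if (is.na(f) && !is.na(s)) {
        b <- .buoyancy(solute, ctx)
        f <- solute$M * b / (.NA * s)
      }
      if (!is.na(eta) && !is.na(Rg)) {
        Phi <- eta * solute$M / (6^(3 / 2) * Rg^3)
      }
      if (!is.na(eta) && !is.na(f)) {
        beta <- (solute$M * eta)^(1 / 3) * ctx$eta0 / (100^(1 / 3) * f)
      }
      if (!is.na(s)) is_ <- s * ctx$eta0 / .buoyancy(solute, ctx)
    }
    if (!is.na(D)) iD <- D * ctx$eta0 / ctx$T
  }
  if (!is.na(beta)) A0 <- .kB * beta
  tibble::tibble(P0 = P0, Phi = Phi, beta = beta, A0 = A0,
                 intrinsic_D = iD, intrinsic_s = is_)
}

#' Approximate molecular weight from viscosity plus diffusion or sedimentation
#'
#' Estimates M by inverting the IT-ratio relation at an assumed value of
#' IT = \eqn{a_I/a_T} (default 1.05, a good rule of thumb for all but very
#' elongated particles).  Two forms are available: the D-form
#' \eqn{M = C_D (T/(\eta_0 D))^3/[\eta]} needs no partial specific volume at
#' all; the s-form \eqn{M = C_s (\eta_0 s/(1-\bar v\rho))^{3/2} [\eta]^{1/2}}
#' does.  At IT = 1.05 and CODATA constants the CGS prefactors are
#' \eqn{C_D = 2.87\times10^{-27}} and \eqn{C_s = 1.42\times10^{25}}.
#' The D-form error scales as the cube of the IT misestimate.
#'
#' @param D Diffusion coefficient (cm^2/s) — D-form.
#' @param s Sedimentation coefficient (s) — s-form; needs `vbar`.
#' @param eta_intr Intrinsic viscosity (cm^3/g).
#' @param ctx A [solvent_context()].
#' @param vbar Partial specific volume (cm^3/g), s-form only.
#' @param IT_assumed Assumed ratio \eqn{a_I/a_T} (default 1.05).
#' @return Estimated molecular weight (Da).
#' @export
molecular_weight_estimate <- function(D = NULL, s = NULL, eta_intr, ctx,
                                      vbar = NULL, IT_assumed = 1.05) {
  ctx <- .as_ctx(ctx)
  stopifnot(eta_intr > 0, IT_assumed > 0)
  if (!is.null(D)) {
    stopifnot(D > 0)
    ## M = IT^3 (k_B/(6 pi))^3 (10 pi N_A/3) * (T/(eta0 D))^3 / [eta]
    pref <- IT_assumed^3 * (.kB / (6 * pi))^3 * 10 * pi * .NA / 3
    return(pref * (ctx$T / (ctx$eta0 * D))^3 / eta_intr)
  }
  if (is.null(s) || is.null(vbar)) {
    abort("Give either `D`, or `s` together with `vbar`.")
  }
  stopifnot(s > 0, vbar > 0)
  b <- 1 - vbar * ctx$rho
  if (b <= 0) abort("Neutral or negative buoyancy: s-form not usable.")
  pref <- sqrt(3 * (6 * pi)^3 * .NA^2 / (10 * pi * IT_assumed^3))
  pref * (ctx$eta0 * s / b)^(3 / 2) * sqrt(eta_intr)
}

#' Exact molecular weight from the Svedberg equation
#'
#' \eqn{M = R T s / (D (1 - \bar v \rho))}.  Exact for any particle; the
#' solvent viscosity cancels.
#'
#' @param s Sedimentation coefficient (s).
#' @param D Diffusion coefficient (cm^2/s).
#' @param solute A [solute_spec()] supplying vbar (its M field is ignored).
#' @param ctx A [solvent_context()].
#' @return Molecular weight (Da).
#' @export
svedberg_molecular_weight <- function(s, D, solute, ctx) {
  ctx <- .as_ctx(ctx); solute <- .as_solute(solute)
  stopifnot(D > 0)
  b <- .buoyancy(solute, ctx)
  .Rgas * ctx$T * s / (D * b)
}

#' Frictional ratio with the hydration adjustment
#'
#' \eqn{f/f_0}, the friction coefficient over that of the sphere of equal
#' (hydrated) volume:
#' \eqn{f/f_0 = f/(6\pi\eta_0) \cdot (4\pi N_A/(3 M \bar v'))^{1/3}} with the
#' hydrated specific volume \eqn{\bar v' = \bar v + \delta/\rho}.  Identical
#' to the ratio of radii \eqn{TV = a_T/a_V(\bar v')} and, for revolution
#' ellipsoids, to the Perrin function \eqn{P(p)}.
#'
#' @param f Friction coefficient (g/s).
#' @param solute A [solute_spec()] (uses M, vbar and delta).
#' @param ctx A [solvent_context()].
#' @return Dimensionless frictional ratio.
#' @export
frictional_ratio_hydrated <- function(f, solute, ctx) {
  ctx <- .as_ctx(ctx); solute <- .as_solute(solute)
  stopifnot(f > 0)
  vbar_h <- solute$vbar + solute$delta / ctx$rho
  f / (6 * pi * ctx$eta0) * (4 * pi * .NA / (3 * solute$M * vbar_h))^(1 / 3)
}
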