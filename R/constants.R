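## Physical constants (CODATA 2018 exact values, CGS units).

.kB <- 1.380649e-16     # Boltzmann constant, erg/K
.NA <- 6.02214076e23    # Avogadro number, 1/mol
.Rgas <- .kB * .NA      # molar gas constant, erg/(mol K)

#' Physical constants used throughout the package
#'
#' Returns the CODATA values of the Boltzmann constant, the Avogadro number
#' and their product, the molar gas constant, in CGS units.  All derived
#' coefficients in this package (the molecular-weight estimator prefactors,
#' the universal-parameter coefficients, the intrinsic diffusion and
#' sedimentation coefficients) trace back to exactly these values.
#'
#' @return A named list with elements `k_B` (erg/K), `N_A` (1/mol) and
#'   `R_gas` (erg/(mol K)), where `R_gas == k_B * N_A` exactly.
#' @examples
#' physical_constants()$k_B
#' @export
physical_constants <- function() {
  list(k_B = .kB, N_A = .NA, R_gas = .Rgas)
}

#' Solvent context
#'
#' Bundles the three solvent-side quantities that convert between particle
#' geometry and measurable properties: absolute temperature, solvent
#' viscosity and solution density.  Defaults are water at 20 degrees C.
#'
#' @param temperature_K Absolute temperature (K).
#' @param viscosity_poise Solvent viscosity \eqn{\eta_0} (poise).
#' @param density_g_cm3 Solution density \eqn{\rho} (g/cm^3); in dilute
#'   solution this is close to the solvent density.
#' @return An object of class `solvent_context`.
#' @examples
#' solvent_context()                       # water, 20 C
#' solvent_context(293.15, 0.01002, 0.998)
#' @export
solvent_context <- function(temperature_K = 293.15,
                            viscosity_poise = 0.01002,
                            density_g_cm3 = 0.99823) {
  stopifnot(is.numeric(temperature_K), is.numeric(viscosity_poise),
            is.numeric(density_g_cm3))
  if (temperature_K <= 0 || viscosity_poise <= 0 || density_g_cm3 <= 0) {
    abort("All solvent-context fields must be strictly positive.")
  }
  structure(list(T = temperature_K, eta0 = viscosity_poise,
                 rho = density_g_cm3),
            class = "solvent_context")
}

#' @export
print.solvent_context <- function(x, ...) {
  cat(sprintf("<solvent_context> T = %g K, eta0 = %g P, rho = %g g/cm^3\n",
              x$T, x$eta0, x$rho))
  invisible(x)
}

#' Solute specification
#'
#' Molar mass, partial specific volume and (optionally) a degree of hydration
#' for a solute species.  The hydrated specific volume used by the frictional
#' ratio is \eqn{\bar v' = \bar v + \delta/\rho}, i.e. the anhydrous volume
#' augmented by the volume of \eqn{\delta} grams of bound water per gram of
#' particle.
#'
#' @param M Molecular weight (Da, i.e. g/mol).
#' @param vbar Partial specific volume (cm^3/g).
#' @param delta Degree of hydration, grams of water per gram of particle
#'   (dimensionless ratio; default 0, anhydrous).
#' @return An object of class `solute_spec`.
#' @examples
#' solute_spec(M = 5e4, vbar = 0.73)
#' solute_spec(M = 5e4, vbar = 0.73, delta = 0.3)
#' @export
solute_spec <- function(M, vbar, delta = 0) {
  stopifnot(is.numeric(M), is.numeric(vbar), is.numeric(delta))
  if (M <= 0) abort("`M` must be positive (Da).")
  if (vbar <= 0) abort("`vbar` must be positive (cm^3/g).")
  if (delta < 0) abort("`delta` must be non-negative (g water / g particle).")
  structure(list(M = M, vbar = vbar, delta = delta), class = "solute_spec")
}

#' @export
print.solute_spec <- function(x, ...) {
  cat(sprintf("<solute_spec> M = %g Da, vbar = %g cm^3/g, delta = %g\n",
              x$M, x$vbar, x$delta))
  invisible(x)
}

## Supported unit tags, grouped by dimension; factors convert to the CGS
## base unit of the group.
.unit_table <- list(
  time_sed = c(S = 1e-13, s = 1),
  length   = c(cm = 1, nm = 1e-7),
  mass     = c(Da = 1, g = NA_real_),   # g per Da filled in below
  spec_vol = c(cm3_per_g = 1, dL_per_g = 100)
)
.unit_table$mass[["g"]] <- .NA  # 1 g = N_A Da

#' Convert between the unit tags used in this package
#'
#' Exact multiplicative conversions between the unit tags that appear in the
#' package's CSV dialects: `S`/`s` (sedimentation coefficient), `cm`/`nm`
#' (length), `Da`/`g` (mass; 1 g = \eqn{N_A} Da) and
#' `cm3_per_g`/`dL_per_g` (intrinsic viscosity; 1 dL/g = 100 cm^3/g).
#'
#' @param value Numeric vector to convert.
#' @param from,to Unit tags; must belong to the same dimension group.
#' @return The converted numeric vector.
#' @examples
#' convert_units(5, "S", "s")          # 5e-13 s
#' convert_units(100, "cm3_per_g", "dL_per_g")  # 1 dL/g
#' convert_units(1, "nm", "cm")        # 1e-7 cm
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value), is.character(from), is.character(to))
  grp_of <- function(u) {
    hit <- vapply(.unit_table, function(g) u %in% names(g), logical(1))
    if (!any(hit)) abort(sprintf("Unknown unit tag '%s'.", u))
    names(.unit_table)[which(hit)[1]]
  }
  gf <- grp_of(from); gt <- grp_of(to)
  if (gf != gt) {
    abort(sprintf(
      "Units '%s' (%s) and '%s' (%s) are not dimensionally compatible.",
      from, gf, to, gt))
  }
  value * .unit_table[[gf]][[from]] / .unit_table[[gt]][[to]]
}

## internal helpers --------------------------------------------------------

.as_ctx <- function(ctx) {
  if (inherits(ctx, "solvent_context")) return(ctx)
  abort("`ctx` must be a solvent_context object; see solvent_context().")
}

.as_solute <- function(solute) {
  if (inherits(solute, "solute_spec")) return(solute)
  abort("`solute` must be a solute_spec object; see solute_spec().")
}

## buoyancy factor with a guard against neutral buoyancy
.buoyancy <- function(solute, ctx, require_positive = FALSE) {
  b <- 1 - solute$vbar * ctx$rho
  if (abs(b) < 1e-12) {
    abort(paste0("Neutral buoyancy: 1 - vbar*rho = 0, the sedimentation ",
                 "coefficient carries no size information."))
  }
  if (require_positive && b <= 0) {
    abort("Negative buoyancy (1 - vbar*rho < 0): species floats.")
  }
  b
}
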