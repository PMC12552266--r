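## Exact revolution-ellipsoid shape functions.
##
## Conventions: a is the symmetry semiaxis, b the equatorial semiaxis,
## p = a/b the axial ratio (p > 1 prolate, p < 1 oblate).  Both branches are
## written in terms of the eccentricity kernels
##   prolate:  e = sqrt(1 - 1/p^2),  L = log((1+e)/(1-e))
##   oblate:   t = sqrt(1/p^2 - 1),  T = atan(t)
## which are the closed forms of the classical ellipsoid shape integrals.
## Near p = 1 both branches suffer 0/0 cancellation and are replaced by
## Taylor expansions about the sphere.

.p1_eps <- 1e-3   # switch to Taylor branch when |p - 1| < .p1_eps

#' Perrin friction function for revolution ellipsoids
#'
#' The exact frictional ratio of a spheroid with axial ratio `p = a/b` to the
#' equal-volume sphere:
#' \deqn{P(p) = \frac{\sqrt{p^2-1}}{p^{1/3}\,\ln(p+\sqrt{p^2-1})} \quad (p>1),
#' \qquad
#' P(p) = \frac{\sqrt{1-p^2}}{p^{1/3}\,\arctan(\sqrt{1-p^2}/p)} \quad (p<1).}
#' \eqn{P(1) = 1} (Stokes law) and \eqn{P(p) \ge 1} everywhere: the sphere
#' minimises friction at fixed volume.  The friction coefficient is
#' \eqn{f = 6\pi\eta_0 (ab^2)^{1/3} P(p)}.
#'
#' @param p Axial ratio(s), strictly positive.
#' @return The dimensionless Perrin function, vectorised over `p`.
#' @examples
#' perrin_function(1)    # 1
#' perrin_function(2)    # 1.0439
#' @export
perrin_function <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p <= 0)) abort("Axial ratio `p` must be strictly positive.")
  vapply(p, .perrin1, numeric(1))
}

.perrin1 <- function(p) {
  if (abs(p - 1) < .p1_eps) {
    eps <- p - 1
    ## series of both branches about the sphere (agree through order 4)
    return(1 + (4 / 45) * eps^2 - (244 / 2835) * eps^3 + (41 / 525) * eps^4)
  }
  if (p > 1) {
    sqrt(p^2 - 1) / (p^(1 / 3) * log(p + sqrt(p^2 - 1)))
  } else {
    sqrt(1 - p^2) / (p^(1 / 3) * atan(sqrt(1 - p^2) / p))
  }
}

#' Simha viscosity factor for revolution ellipsoids
#'
#' The exact zero-shear Einstein viscosity coefficient \eqn{\nu(p)} of a
#' rigid spheroid under dominant rotational Brownian motion, defined by
#' \eqn{[\eta] = \nu N_A V_p / M}.  \eqn{\nu(1) = 5/2} (Einstein's sphere
#' value); the factor grows on both the prolate and the oblate side.
#'
#' The implementation assembles the orientation-averaged flow stresslet of
#' the torque-free spheroid and the direct Brownian stress from the exact
#' resistance functions of the ellipsoid (closed forms in
#' \eqn{\log}/\eqn{\arctan} of the classical shape integrals); see the
#' methods vignette for the derivation and its validation against an
#' independent quadrature oracle, the sphere limit and the classical
#' large-p asymptote
#' \eqn{14/15 + p^2/(15(\ln 2p - 3/2)) + p^2/(5(\ln 2p - 1/2))}.
#'
#' @param p Axial ratio(s), strictly positive.
#' @return The dimensionless viscosity factor, vectorised over `p`.
#' @examples
#' simha_factor(1)    # 2.5
#' simha_factor(2)    # 2.9076
#' @export
simha_factor <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p <= 0)) abort("Axial ratio `p` must be strictly positive.")
  vapply(p, .simha1, numeric(1))
}

## Stresslet resistance functions of the spheroid, normalised by
## (20/3) pi eta0 a^3 (strain responses) and 8 pi eta0 a^3 (rotation),
## with a the symmetry semiaxis:
##   XM: axisymmetric strain; ZM: equatorial-plane strain;
##   YM: meridian-plane strain, particle held; Yrot: stresslet per unit
##   relative rotation rate; YC: transverse rotational resistance.
.spheroid_resistances <- function(p) {
  if (p > 1) {
    e <- sqrt(1 - 1 / p^2); L <- log((1 + e) / (1 - e))
    list(
      XM = (8 / 15) * e^5 / ((3 - e^2) * L - 6 * e),
      ZM = (16 / 5) * e^5 * (1 - e^2) /
        (3 * (1 - e^2)^2 * L - 2 * e * (3 - 5 * e^2)),
      YM = (4 / 5) * e^5 * (2 * e * (1 - 2 * e^2) - (1 - e^2) * L) /
        ((2 * e - (1 + e^2) * L) *
           (2 * e * (3 - 2 * e^2) - 3 * (1 - e^2) * L)),
      Yrot = (4 / 5) * e^5 / (2 * e - (1 + e^2) * L),
      YC = (4 / 3) * e^3 * (2 - e^2) / ((1 + e^2) * L - 2 * e),
      shrink = 1 - e^2)   # (b/a)^2
  } else {
    t <- sqrt(1 / p^2 - 1); Ta <- atan(t)
    list(
      XM = (4 / 15) * t^5 / ((3 + t^2) * Ta - 3 * t),
      ZM = (8 / 5) * t^5 * (1 + t^2) /
        (3 * (1 + t^2)^2 * Ta - t * (3 + 5 * t^2)),
      YM = -(2 / 5) * t^5 * ((1 + t^2) * Ta - t * (1 + 2 * t^2)) /
        ((t - (1 - t^2) * Ta) *
           (t * (3 + 2 * t^2) - 3 * (1 + t^2) * Ta)),
      Yrot = (2 / 5) * t^5 / (t - (1 - t^2) * Ta),
      YC = (2 / 3) * t^3 * (2 + t^2) / (t - (1 - t^2) * Ta),
      shrink = 1 + t^2)
  }
}

.simha1 <- function(p) {
  if (abs(p - 1) < .p1_eps) {
    eps <- p - 1
    return(2.5 + (26 / 35) * eps^2 - 0.6724198231 * eps^3 +
             0.6756627304 * eps^4)
  }
  rs <- .spheroid_resistances(p)
  B <- (p^2 - 1) / (p^2 + 1)   # Jeffery orbit constant
  flow <- (rs$XM + 2 * rs$ZM + 2 * (rs$YM + B * rs$Yrot)) / (2 * rs$shrink)
  brown <- (3 / 5) * B^2 * rs$YC / rs$shrink
  flow + brown
}

#' Revolution-ellipsoid model
#'
#' Constructs a spheroid either from its two semiaxes `(a, b)` or from its
#' axial ratio and volume-equivalent radius `(p, aV)`, where
#' \eqn{a_V = (a b^2)^{1/3}}.
#'
#' @param a Symmetry semiaxis (cm).
#' @param b Equatorial semiaxis (cm).
#' @param p Axial ratio a/b (alternative parameterisation, with `aV`).
#' @param aV Volume-equivalent radius (cm).
#' @return An object of class `spheroid` with fields `a`, `b`, `p`.
#' @examples
#' spheroid(a = 4e-7, b = 1e-7)
#' spheroid(p = 4, aV = 3e-7)
#' @export
spheroid <- function(a = NULL, b = NULL, p = NULL, aV = NULL) {
  if (!is.null(a) && !is.null(b)) {
    if (!(a > 0 && b > 0)) abort("Semiaxes must be strictly positive.")
  } else if (!is.null(p) && !is.null(aV)) {
    if (!(p > 0 && aV > 0)) {
      abort("Axial ratio and volume radius must be strictly positive.")
    }
    a <- aV * p^(2 / 3)
    b <- aV * p^(-1 / 3)
  } else {
    abort("Give either (a, b) or (p, aV).")
  }
  structure(list(a = a, b = b, p = a / b), class = "spheroid")
}

#' @export
print.spheroid <- function(x, ...) {
  cat(sprintf("<spheroid> a = %g cm, b = %g cm, p = %g (%s)\n",
              x$a, x$b, x$p,
              if (x$p > 1) "prolate" else if (x$p < 1) "oblate" else "sphere"))
  invisible(x)
}

#' Equivalent radii of a revolution ellipsoid
#'
#' Computes all four equivalent radii of a spheroid from its exact shape
#' functions:
#' \eqn{a_T = (ab^2)^{1/3} P(p)}, \eqn{a_I = (2\nu(p)/5)^{1/3} (ab^2)^{1/3}},
#' \eqn{a_G = \sqrt{(a^2+2b^2)/3}} and \eqn{a_V = (ab^2)^{1/3}}.
#' For a sphere all four equal the radius.
#'
#' @param sph A [spheroid()] (or anything accepted by its constructor via
#'   `...`).
#' @param ... Passed to [spheroid()] when `sph` is not already a spheroid.
#' @return A one-row tibble with columns `aT`, `aI`, `aG`, `aV` (cm) plus
#'   `p`.
#' @examples
#' spheroid_radii(spheroid(p = 4, aV = 3e-7))
#' @export
spheroid_radii <- function(sph = NULL, ...) {
  if (!inherits(sph, "spheroid")) sph <- spheroid(...)
  aV <- (sph$a * sph$b^2)^(1 / 3)
  tibble::tibble(
    aT = aV * perrin_function(sph$p),
    aI = (2 * simha_factor(sph$p) / 5)^(1 / 3) * aV,
    aG = sqrt((sph$a^2 + 2 * sph$b^2) / 3),
    aV = aV,
    p = sph$p)
}

## --- quadrature oracles (used by the test suite; exported because they are
## legitimate, if slow, alternatives to the closed forms) ------------------

#' Perrin function by numerical quadrature of the Oberbeck integrals
#'
#' Independent evaluation of the spheroid friction: the Oberbeck resistance
#' along each principal axis, \eqn{f_i = 16\pi\eta_0/(\chi + a_i^2\alpha_i)}
#' with \eqn{\chi,\alpha_i} the classical ellipsoid shape integrals computed
#' by adaptive quadrature, orientation-averaged through
#' \eqn{3/f = \sum_i 1/f_i} and normalised by the equal-volume sphere.
#' Used as the brute-force oracle for [perrin_function()].
#'
#' @param p Axial ratio (scalar).
#' @return The Perrin function value.
#' @export
perrin_function_quadrature <- function(p) {
  stopifnot(p > 0)
  a <- p; b <- 1
  Dl <- function(l) sqrt(a^2 + l) * (b^2 + l)
  qint <- function(f) {
    integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value
  }
  chi <- qint(function(l) 1 / Dl(l))
  al_a <- qint(function(l) 1 / ((a^2 + l) * Dl(l)))
  al_b <- qint(function(l) 1 / ((b^2 + l) * Dl(l)))
  fa <- 16 * pi / (chi + a^2 * al_a)
  fb <- 16 * pi / (chi + b^2 * al_b)
  f_avg <- 3 / (1 / fa + 2 / fb)
  f_avg / (6 * pi * (a * b^2)^(1 / 3))
}

#' Simha factor with quadrature-evaluated shape kernels
#'
#' Independent evaluation of [simha_factor()] in which the transcendental
#' kernel of every resistance function (the \eqn{\log}/\eqn{\arctan} of the
#' closed forms) is replaced by adaptive quadrature of the classical
#' ellipsoid integral \eqn{\chi = \int_0^\infty d\lambda/\Delta(\lambda)},
#' \eqn{\Delta = (a^2+\lambda)^{1/2}(b^2+\lambda)}, of which it is the
#' closed form (\eqn{L = c\,\chi} prolate, \eqn{T = c'\chi/2} oblate).
#'
#' @param p Axial ratio (scalar).
#' @return The Simha viscosity factor.
#' @export
simha_factor_quadrature <- function(p) {
  stopifnot(p > 0, p != 1)
  a <- p; b <- 1
  Dl <- function(l) sqrt(a^2 + l) * (b^2 + l)
  chi <- integrate(function(l) 1 / Dl(l), 0, Inf,
                   rel.tol = 1e-12, abs.tol = 0)$value
  B <- (p^2 - 1) / (p^2 + 1)
  if (p > 1) {
    e <- sqrt(1 - 1 / p^2)
    L <- sqrt(a^2 - b^2) * chi        # = log((1+e)/(1-e)) by quadrature
    XM <- (8 / 15) * e^5 / ((3 - e^2) * L - 6 * e)
    ZM <- (16 / 5) * e^5 * (1 - e^2) /
      (3 * (1 - e^2)^2 * L - 2 * e * (3 - 5 * e^2))
    YM <- (4 / 5) * e^5 * (2 * e * (1 - 2 * e^2) - (1 - e^2) * L) /
      ((2 * e - (1 + e^2) * L) *
         (2 * e * (3 - 2 * e^2) - 3 * (1 - e^2) * L))
    Yrot <- (4 / 5) * e^5 / (2 * e - (1 + e^2) * L)
    YC <- (4 / 3) * e^3 * (2 - e^2) / ((1 + e^2) * L - 2 * e)
    shrink <- 1 - e^2
  } else {
    t <- sqrt(1 / p^2 - 1)
    Ta <- sqrt(b^2 - a^2) * chi / 2   # = atan(t) by quadrature
    XM <- (4 / 15) * t^5 / ((3 + t^2) * Ta - 3 * t)
    ZM <- (8 / 5) * t^5 * (1 + t^2) /
      (3 * (1 + t^2)^2 * Ta - t * (3 + 5 * t^2))
    YM <- -(2 / 5) * t^5 * ((1 + t^2) * Ta - t * (1 + 2 * t^2)) /
      ((t - (1 - t^2) * Ta) *
         (t * (3 + 2 * t^2) - 3 * (1 + t^2) * Ta))
    Yrot <- (2 / 5) * t^5 / (t - (1 - t^2) * Ta)
    YC <- (2 / 3) * t^3 * (2 + t^2) / (t - (1 - t^2) * Ta)
    shrink <- 1 + t^2
  }
  (XM + 2 * ZM + 2 * (YM + B * Yrot)) / (2 * shrink) +
    (3 / 5) * B^2 * YC / shrink
}
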