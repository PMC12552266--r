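## Wormlike (Kratky-Porod) chain geometry and flexible-coil limits.

#' Radius of gyration of an ideal wormlike chain (Benoit--Doty)
#'
#' \deqn{R_g^2 = \frac{LP}{3} - P^2 + \frac{2P^3}{L}
#'   - \frac{2P^4}{L^2}\left(1 - e^{-L/P}\right)}
#' for a chain of contour length `L` and persistence length `P` without
#' excluded volume.  Limits: rigid rod \eqn{R_g^2 \to L^2/12} for
#' \eqn{L \ll P}; Gaussian coil \eqn{R_g^2 \to LP/3} for \eqn{L \gg P}.
#' A series expansion replaces the closed form for \eqn{L/P < 10^{-2}}
#' where the four terms cancel catastrophically.
#'
#' @param L Contour length (any length unit).
#' @param P Persistence length (same unit).
#' @return Radius of gyration in the same unit, vectorised.
#' @examples
#' wlc_gyration_radius(100, 50)
#' wlc_gyration_radius(1, 1)    # 0.2629 * P
#' @export
wlc_gyration_radius <- function(L, P) {
  stopifnot(all(L > 0), all(P > 0))
  x <- L / P
  rg2_red <- ifelse(
    x < 1e-2,
    ## 2 * sum_{n>=4} (-1)^n x^(n-2) / n!
    x^2 / 12 - x^3 / 60 + x^4 / 360 - x^5 / 2520 + x^6 / 20160,
    x / 3 - 1 + 2 / x - (2 / x^2) * (1 - exp(-x)))
  P * sqrt(rg2_red)
}

#' Contour length from mass and mass per unit length
#'
#' `L = M / M_L`.
#'
#' @param M Molecular weight (Da).
#' @param M_L Mass per unit length (Da/nm).
#' @return Contour length (nm).
#' @export
wlc_contour_length <- function(M, M_L) {
  stopifnot(all(M > 0), all(M_L > 0))
  M / M_L
}

#' Contour length and mass of B-form duplex DNA
#'
#' Watson--Crick arithmetic for double-stranded DNA: contour length
#' \eqn{L = l_{bp} n_{bp}} with a rise per base pair of 0.34 nm, and mass
#' \eqn{M = M_{bp} n_{bp}} with a compromise base-pair mass of 640 Da
#' (between the sodium-salt and free-acid conventions).  The implied mass
#' per unit length is \eqn{M_L = M_{bp}/l_{bp} = 1882} Da/nm.
#'
#' @param n_bp Number of base pairs.
#' @param l_bp Rise per base pair (nm, default 0.34).
#' @param M_bp Average base-pair mass (Da, default 640).
#' @return A tibble with columns `n_bp`, `L_nm`, `M_Da`, `M_L_Da_nm`.
#' @examples
#' dna_contour(12)   # a dodecamer: L = 4.08 nm
#' @export
dna_contour <- function(n_bp, l_bp = 0.34, M_bp = 640) {
  stopifnot(all(n_bp > 0), l_bp > 0, M_bp > 0)
  tibble::tibble(n_bp = n_bp, L_nm = l_bp * n_bp, M_Da = M_bp * n_bp,
                 M_L_Da_nm = M_bp / l_bp)
}

#' Asymptotic flexible-coil ratios of radii
#'
#' The high-molecular-weight ratios GT, GI (and IT = GT/GI) of fully
#' flexible linear chains, obtained from the simulation-determined Flory
#' parameters through the ratio relations \eqn{P_0 = \sqrt{10}\pi/GT} and
#' \eqn{\Phi = 9.23\times10^{23}/GI^3}: in a theta (ideal) solvent
#' \eqn{P_0 = 6.0}, \eqn{\Phi = 2.53\times10^{23}}; in a good solvent with
#' excluded volume \eqn{P_0 = 5.3}, \eqn{\Phi = 1.9\times10^{23}}.
#'
#' @param solvent_regime `"theta"` or `"good"`.
#' @return A one-row tibble with `GT`, `GI`, `IT`, `P0`, `Phi`.
#' @examples
#' coil_limit_ratios("theta")   # GT = 1.655, GI = 1.539
#' @export
coil_limit_ratios <- function(solvent_regime = c("theta", "good")) {
  solvent_regime <- match.arg(solvent_regime)
  pars <- switch(solvent_regime,
                 theta = list(P0 = 6.0, Phi = 2.53e23),
                 good  = list(P0 = 5.3, Phi = 1.9e23))
  GT <- .P0_coef / pars$P0
  GI <- (.Phi_coef / pars$Phi)^(1 / 3)
  tibble::tibble(GT = GT, GI = GI, IT = GT / GI,
                 P0 = pars$P0, Phi = pars$Phi)
}
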