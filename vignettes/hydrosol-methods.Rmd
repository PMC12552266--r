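---
title: "Models and methods behind hydrosol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hydrosol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrosol)
library(dplyr)
```

hydrosol implements a consistent formalism for the dilute-solution
hydrodynamics of macromolecules and nanoparticles, together with forward
models of sedimentation-velocity experiments and a two-dimensional
inversion of sedimentation scans.  This vignette explains the models,
their assumptions, the numerical choices, and what the package's synthetic
tests do and do not demonstrate about real data.

## Units and constants

Everything internal is strict CGS (cm, g, s, erg, poise), because the
classical coefficients of this field ($2.86\times10^{-27}$,
$1.41\times10^{25}$, $7.32\times10^{-18}$, $8.81\times10^{-26}$,
$2.112\times10^6$) are CGS numbers.  User-facing code accepts nm, Da,
svedberg and dL/g at the boundary (`convert_units()`).  The CODATA values
$k_B = 1.380649\times10^{-16}$ erg/K and
$N_A = 6.02214076\times10^{23}$ mol$^{-1}$ are frozen in
`physical_constants()`; every derived coefficient in the package traces to
them, which is what the constants fingerprint test asserts.

## Equivalent radii and ratios of radii

Measured solution properties mix the particle's geometry with solvent and
composition quantities.  The package therefore works wherever possible in
*equivalent radii* — the radius of the sphere sharing one property with
the particle:

* $a_T = f/(6\pi\eta_0) = k_BT/(6\pi\eta_0 D) = M(1-\bar v\rho)/(6\pi\eta_0 N_A s)$
  (translational; the Stokes radius $R_{H,f}$),
* $a_I = (3M[\eta]/(10\pi N_A))^{1/3}$ (viscometric, $R_{H,\eta}$),
* $a_G = \sqrt{5/3}\,R_g$ (gyration),
* $a_V = (3M\bar v/(4\pi N_A))^{1/3}$ (anhydrous volume).

Radii are intrinsic to the particle: the test suite generates observables
at two different solvent contexts from one radius and recovers the same
radius.  Ratios $XY = a_X/a_Y$ (IT, GT, GI, TV, IV) are dimensionless
shape indicators, all equal to 1 for a sphere, with the combination
identity $IT \cdot GI = GT$.  The classical universal parameters are thin
wrappers over these ratios: $P_0 = \sqrt{10}\pi/GT$,
$\Phi = 9.23\times10^{23}/GI^3$, $\beta = 2.112\times10^6\,IT$, and the
Tsvetkov invariant $A_0 = k_B\beta$.  The $\Phi$ coefficient is derived
from the definitions rather than transcribed, and the package checks the
raw-property route against the ratio route to $10^{-10}$ relative.

Two unit conventions coexist historically: $\beta$ and $A_0$ are defined
with $[\eta]$ in dL/g.  The $100^{-1/3}$ factor is applied inside those
two formulas only; everywhere else $[\eta]$ is cm$^3$/g.

**Hydration.** The frictional ratio compares $a_T$ with the sphere of
equal *hydrated* volume.  We use $\bar v' = \bar v + \delta/\rho$ —
the anhydrous volume plus the volume of $\delta$ grams of water per gram
of particle — which is the standard hydrated-volume convention and is
dimensionally consistent (a multiplicative form $\bar v(1+\delta/\rho)$
circulates in the literature but mixes units).

**Approximate molecular weights.** Combining $[\eta]$ with $D$ (or $s$)
under an assumed $IT$ gives a practical $M$ estimator that, in its D-form,
needs no $\bar v$ at all.  The default $IT = 1.05$ is a good rule of
thumb for everything except very elongated particles; the D-form error is
cubic in the $IT$ misestimate, so a true sphere analysed at 1.05 comes
out high by $1.05^3 \approx 16\%$ — the documented worst case of the
recommended range.  Note that the D-form and s-form agree with each other
(and with the truth) exactly when the particle's true $IT$ equals the
assumed one; for any other particle they bracket the truth from opposite
sides.

## Spheroid shape functions

For revolution ellipsoids (symmetry semiaxis $a$, equatorial $b$,
$p = a/b$) the package provides the exact Perrin friction function and
the exact zero-shear Simha viscosity factor.

`perrin_function()` implements the classical closed forms
($\log$ branch for prolate, $\arctan$ for oblate) and is validated
against an independent quadrature oracle: the Oberbeck resistance
$f_i = 16\pi\eta_0/(\chi + a_i^2\alpha_i)$ with the ellipsoid shape
integrals $\chi,\alpha_i$ evaluated by adaptive quadrature,
orientation-averaged harmonically and normalised by the equal-volume
sphere (`perrin_function_quadrature()`).

`simha_factor()` required more care because no closed form is printed in
most modern sources.  We derived it from first principles: the Stokes
linear-flow problems around a prolate spheroid (axisymmetric strain,
equatorial strain, meridian shear with torque-free rotation, and pure
rotation) were solved exactly with a line-singularity method, the five
stresslet/rotation resistance functions were identified as closed forms
in the eccentricity kernels, and the zero-shear intrinsic viscosity was
assembled as the isotropic orientation average of the flow stresslet plus
the direct Brownian stress
$\nu_B = \tfrac{3}{5}B^2 Y^C/(1-e^2)$, where
$B = (p^2-1)/(p^2+1)$ is the Jeffery orbit constant and $Y^C$ the
transverse rotation resistance.  The oblate branch follows by analytic
continuation ($e \to i\varepsilon$, $\log \to 2i\arctan$).  The result
satisfies, analytically or to $10^{-13}$ numerically:

* $\nu(1) = 5/2$ (Einstein's sphere value), minimum of the curve;
* the classical rod asymptote
  $14/15 + p^2/(15(\ln 2p - 3/2)) + p^2/(5(\ln 2p - 1/2))$
  (0.07% at $p=100$); the second term is reproduced *analytically* by the
  Brownian part, a strong independent check;
* literature table values ($\nu = 2.908$ at $p = 2$; $2.854$, $4.708$,
  $8.04$ at $1/p = 2, 5, 10$).

Both functions switch to fourth-order Taylor expansions about $p = 1$
for $|p-1| < 10^{-3}$, where the closed forms lose up to seven digits to
cancellation ($e^5$ against differences of logarithms).

`spheroid_radii()` maps a spheroid to all four equivalent radii:
$a_T = (ab^2)^{1/3}P(p)$, $a_I = (2\nu/5)^{1/3}(ab^2)^{1/3}$,
$a_G = \sqrt{(a^2+2b^2)/3}$ (from $R_g^2 = (a^2+2b^2)/5$),
$a_V = (ab^2)^{1/3}$.  The resulting IT ratio stays within about 2% of
unity on the whole oblate side while rising without bound for prolate
shapes — the quantitative basis for the $IT \approx 1.05$ rule of thumb
and its elongated-particle failure mode.

## Wormlike chains

`wlc_gyration_radius()` is the Benoit–Doty radius of gyration of the
ideal (unperturbed) Kratky–Porod chain.  For $L/P < 10^{-2}$ the closed
form cancels catastrophically and a series (through $(L/P)^6$) is used;
the rod ($L^2/12$) and coil ($LP/3$) limits and monotonicity in both
arguments are tested.  Excluded-volume expansion is out of scope; the
good-solvent coil *ratios* are instead provided as constants
(`coil_limit_ratios()`) derived from the simulation-determined Flory
parameters ($P_0 = 6.0$, $\Phi = 2.53\times10^{23}$ ideal;
$P_0 = 5.3$, $\Phi = 1.9\times10^{23}$ good solvent).  B-DNA arithmetic
(`dna_contour()`) uses a rise of 0.34 nm/bp and a compromise base-pair
mass of 640 Da (between the salt and free-acid conventions), giving
$M_L = 1882$ Da/nm.

## The global-fit statistic

`delta_metric()` is the percent-RMS deviation between model and reference
equivalent radii, with equal weights within and across species:
$$\Delta^2 = \frac{1}{n_{sp}}\sum_{sp}\frac{1}{n_X}\sum_X
\left(\frac{a_X - a_{X,ref}}{a_{X,ref}}\right)^2,\qquad
\Delta_\% = 100\sqrt{\Delta^2}.$$
Species may carry different property sets; $n_X$ is per species.  An
inverse-variance-weighted variant was deliberately not added: equal
weighting is the defining convention of the statistic, and mixing
conventions invites silent incomparability between fits.

`hydfit()` minimises $\Delta_\%$ over a box by a coarse log-spaced grid
(default 25 points/parameter) followed by Nelder–Mead polish (Brent in
one dimension).  The landscape is cheap and low-dimensional but can be
multimodal — an oblate/prolate mirror valley is common — so the polish is
started from the five best grid cells and the best polished result is
kept.  With fewer than two distinct properties per species the problem
is under-determined; `profile_landscape()` exists precisely to make such
degeneracy valleys visible before one trusts a point estimate.

## Sedimentation-velocity forward models

A sedimenting, non-interacting species is fully described by the
hydrodynamic radius $R_{H,f}$ and the buoyant particle mass
$m^{(b)} = m(1-\bar v\rho)$: $f = 6\pi\eta_0R_H$, $s = m^{(b)}/f$,
$D = k_BT/f$.  Three forward models are provided.

**Analytic (no diffusion).**  $\ln(r/r_m) = \omega^2 s t$; the classical
boundary-velocity analysis.

**Brownian dynamics.**  Per step,
$\Delta r_{sed} = r(e^{s\omega^2\Delta t}-1)$ plus a Gaussian step of
variance $2D\Delta t$.  The exponential form makes the deterministic part
exact for any step size; a warning is raised when
$e^{s\omega^2\Delta t}-1 > 0.01$, where the superposition with the
diffusive step degrades.  Boundary conditions are reflection at the
meniscus and absorption ("pellet") at the bottom, chosen so that cell
mass bookkeeping stays exact; initial positions are distributed
proportional to $r$ and concentrations estimated as bin count$/(r\,
\Delta r)$, both reflecting sector geometry.

**Lamm equation.**  The transport equation is discretised in conservative
flux form $\partial_t c = \frac1r\partial_r[r(D\partial_r c -
s\omega^2 r c)]$ on a uniform grid of cell centres (default 400),
zero-flux at both ends, with exponentially fitted (Scharfetter–Gummel)
face fluxes and a fully implicit time step.  This combination yields an
M-matrix: the update is positivity-preserving at any step size, conserves
the sector mass $\sum_i c_i r_i \Delta r$ to round-off, and represents
the plateau-dilution mode $\dot c = -2s\omega^2c$ exactly in space.  A
Crank–Nicolson step would be second order in time but oscillates at sharp
boundaries, producing small negative concentrations that the solver's own
negativity guard (at $-10^{-9}c_0$) is designed to reject; we prefer the
unconditionally positive first-order scheme and control its temporal
error — an artificial boundary broadening of order $v^2\Delta t/2$ — via
the Courant-targeted default step ($s\omega^2 r_b\Delta t/\Delta r \le
0.5$, tunable via `courant`).  At the package's reference conditions
(about 6 S, 50 kDa-like particle at 50,000 rpm in a 6.0–7.2 cm cell)
this error is a few percent of $D$ and the solver agrees with the
unbiased Brownian-dynamics engine to the BD sampling error
(L2 difference scaling as $n^{-1/2}$ up to $10^5$ particles).

`fit_s_from_boundary()` implements midpoint boundary tracking: per scan
the boundary is located where the signal crosses the mid-level between
the solvent and solution plateaus (found adaptively from the
steepest-rise position), and $\omega^2 s$ is the least-squares slope of
$\ln(r_{mid}/r_m)$ against time.  Scans whose boundary has not cleared
the meniscus, or sits too close to the bottom pile-up, are skipped; at
least three usable scans are required.  Closed-loop recovery at the
reference conditions is within 2% (Lamm) and within sampling error (BD).

**f/f0 conversions.**  The identities used by modern analysis software to
supply $D$ from $s$ and an assumed frictional ratio are implemented in
both published algebraic arrangements (they are identical since
$R = k_BN_A$), and the inverse map $f/f_0(s, D)$ is the exact algebraic
inversion — the exponent of the buoyancy-volume factor is $1/3$, as
required for `ff0_from_s_D(diffusion_from_s_ff0(...))` to round-trip to
$10^{-12}$.

## The 2D inversion in $(R_H, m^{(b)})$

Because the full time course of sedimentation depends only on $R_H$,
$m^{(b)}$ and $\eta_0$, scan sets can be analysed as a non-negative
distribution $c(R_H, m^{(b)})$ *without knowing the partial specific
volume* — unlike $(s, f/f_0)$ or $(s, D)$ presentations, which need a
common $\bar v$ to be interpreted.  $\bar v$ enters only if the result is
converted (`convert_distribution()`) to conventional coordinates, where
each node maps exactly through $s = m^{(b)}/(6\pi\eta_0R_H)$,
$D = k_BT/(6\pi\eta_0R_H)$, $M = N_Am^{(b)}/(1-\bar v\rho)$ and
$f/f_0 = R_H/a_V$.

The inversion solves $\min_{w\ge0}\|Aw - z\|^2 + \lambda^2\|w\|^2$ by
Lawson–Hanson active-set NNLS on the ridge-augmented system, with the
design matrix built from unit-concentration Lamm solves at every node of
a log-spaced grid (default $20\times20$; $s$ and $D$ span decades).
Numerical choices that matter:

* the design solves default to the radial resolution of the data, so
  that forward discretisation error largely cancels between data and
  design (a 150- vs 300-point mismatch contributes an 8% L2 model error
  that overwhelms 0.5% noise);
* $\lambda$ defaults to a discrepancy-principle choice: the largest value
  on a short ladder whose residual RMS stays at or below the recorded
  scan noise, falling back to $\lambda = 0$;
* radius subsampling (every $k$-th point) keeps the matrix at desk
  scale and is recorded in the output;
* peak extraction uses connected components above 5% of the maximum
  weight with a Chebyshev gap of 2 cells, because NNLS solutions are
  spiky and one off-node species typically appears as a cluster of
  near-adjacent spikes; centroids are weight-averaged in log space.

At the reference two-species conditions (2 nm/2.25e-20 g and
4 nm/9.0e-20 g, equal loadings, 0.5% of loading as signal noise) the
recovered centroids land within about 0.1 grid cell of truth and the
total recovered signal matches the loading within the noise.

## What the synthetic generators do and do not emulate

`synthetic_property_dataset()` draws per-radius multiplicative Gaussian
noise around exact model radii; `synthetic_auc_dataset()` adds white
Gaussian signal noise to a forward simulation.  These reproduce the
*magnitudes* typical of good measurements (percent-level property errors,
sub-percent scan noise) but none of the structured pathologies of real
data: concentration-dependent non-ideality ($k_s$, Huggins coefficient),
charge effects, time- and radially-correlated detector noise, meniscus
artefacts, or inter-laboratory systematic offsets.  Passing closed-loop
tests therefore demonstrates the correctness and internal consistency of
the algorithms, not robustness to every experimental artefact.

Problem sizes used throughout the tests — 300–400 radial cells, scan
schedules of 4–9 scans over 1–1.5 h of run time, $10^4$–$10^5$ BD
particles, $20\times20$ inversion grids — were chosen once as
representative of a desk-scale analysis of a single AUC cell and are
stated here as the package's reference study conditions.

## Known limitations

* The Lamm solver is first-order in time; boundary shapes carry a small
  systematic broadening unless `courant` is lowered.  Pressure effects,
  co-sedimenting gradients and reacting systems are out of scope.
* The wormlike-chain module covers geometry ($R_g$, contour arithmetic)
  only; wormlike *hydrodynamic* radii require simulation-derived surfaces
  that are not shipped, though such models plug into `hydfit()` through
  the user-model interface if the user supplies them.
* Cylinders and triaxial ellipsoids are not implemented.
* Uncertainty propagation in `equivalent_radii()` is first-order only.
* The dilute-solution assumption is absolute: no concentration-dependence
  corrections anywhere.
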