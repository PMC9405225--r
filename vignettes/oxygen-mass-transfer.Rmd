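---
title: "Oxygen mass transfer and hydrodynamics in Vertical-Wheel bioreactors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oxygen mass transfer and hydrodynamics in Vertical-Wheel bioreactors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwoxy)
```

## The problem

Small Vertical-Wheel bioreactors (60-100 mL working volume, a vertically
oriented paddle wheel over a U-shaped bottom) are surface-aerated: there is no
sparging, and all oxygen enters the culture through the free gas-liquid
interface. For oxygen-hungry stem-cell cultures the attainable cell density is
therefore often limited by the volumetric mass-transfer coefficient
$k_La$, and the agitation rate that raises it also raises the shear stress
that damages cell aggregates. `vwoxy` implements the complete desk-side
analysis of this trade-off:

1. estimation of $k_La$ from luminescence-quenching aeration traces,
2. a modified Sherwood correlation that maps operating conditions to $k_L$,
3. the oxygen-limited cell-density bound $X = k_La\,C_{sat}/q_{O_2}$, and
4. post-processing statistics for large-eddy-simulation (LES) exports:
   WALE eddy viscosity, energy dissipation rate, Kolmogorov scale, shear
   stress, resolved-kinetic-energy ratio and surface-flux $k_L$.

Every input the pipeline consumes can be produced by a seeded synthetic
generator with known ground truth, so each stage is testable end to end
without instrument or solver output.

## Aeration kinetics and the $k_La$ fit

A deaerated reactor re-aerating at fixed conditions follows

$$\frac{dC_{O_2}}{dt} = k_La\,(C_{sat} - C_{O_2}),
  \qquad C_{O_2}(0) = 0
  \;\Rightarrow\; C_{O_2}(t) = C_{sat}\,(1 - e^{-k_La\,t}).$$

Dissolved oxygen quenches the luminescence of a ruthenium dye, so the
recorded peak intensity (at 608 nm) *decreases* as oxygen enters. The
treatment inverts this: with $I_{max}$ the intensity at full deaeration and
$I_{min}$ at saturation,

$$I_{treated}(t) = I_{max} - I_{recorded}(t), \qquad
  I_{calc}(t) = (I_{max} - I_{min})\,(1 - e^{-k_La\,t}),$$

and `fit_kla()` minimises $\sum_t (I_{treated} - I_{calc})^2$ over
$k_La > 0$.

Numerical choices:

* The minimisation is a bounded scalar search on $\log k_La$ over
  $[10^{-6}, 10^{-1}]\,\mathrm{s^{-1}}$ with tolerance $10^{-10}$ —
  deterministic, derivative-free, no seed. A solution on the bracket is
  flagged (`boundary = TRUE`) rather than silently returned.
* $I_{max}$ and $I_{min}$ are fixed from the experiment, as the protocol
  implies (the plateaus are recorded); when a bare trace lacks them they are
  approximated by leading/trailing plateau medians, which is documented as
  approximate because a trace that starts decaying immediately has no true
  leading plateau. `fix_endpoints = FALSE` instead frees the span in a
  Levenberg-Marquardt fit.
* Spectral treatment (`extract_peak()`): dark-spectrum subtraction, baseline
  drift removal anchored on an emission-free band (default 450-500 nm; the
  drift is an additive offset from equipment temperature variations, so
  subtracting the band mean removes it whatever its time dependence), a
  30-point moving average mirroring the acquisition smoothing, then the
  window maximum at $608 \pm 10$ nm.
* An optional initial concentration $C_0$ relaxes the absolute-deaeration
  assumption in `concentration_profile()` / `integrate_aeration()`.

A single fixed $k_La$ cannot follow a run in which the transfer coefficient
drifts: fitted on such a trace it over-predicts the early points and
under-predicts the late ones. The suite encodes this as a signed-residual
ordering on a trace generated with a ramping $k_La(t)$.

## The modified Sherwood correlation

Dimensionless groups (impeller convention, characteristic length = wheel
diameter $D$):

$$Re = \frac{N D^2}{\nu}, \qquad Sc = \frac{\nu}{D_{AB}}, \qquad
  Sh = \frac{k_L D}{D_{AB}}, \qquad G = \frac{D\,A}{V},$$

where $G$ — wheel diameter over equivalent liquid height $V/A$ — absorbs
working-volume changes. The correlation is

$$Sh = k\,Re^{\alpha}\,Sc^{1/3}\,G^{\gamma},$$

with the Schmidt exponent pinned at the standard $1/3$, which keeps the
correlation usable up to 37 °C.

Design choices that were genuinely open:

* **Characteristic length.** The wheel diameter is used in both $Re$ and
  $Sh$; this convention reproduces the upper end of the fitted Reynolds
  range (≈3170 near 95.5 rpm) together with the geometric-number fit-range
  endpoints, which a liquid-height convention does not. It is configurable.
* **Wheel diameter default.** $D = 0.0414$ m, obtained by dividing the
  geometric-number fit-range endpoints (0.651, 1.08) by the corresponding
  specific areas (15.7, 26.1 m⁻¹) from the packaged area table. Both
  quotients agree to three digits, which is the consistency check behind the
  default. Overridable in `operating_point()` and the run config.
* **Objective space.** `fit_sherwood()` minimises squared error on $Sh$
  directly (the correlation as written); a log-space objective is available
  for diagnostics. The linear-space solve is a deterministic
  Levenberg-Marquardt refinement *started from the exact log-space OLS
  solution* — for noise-free data that start is already the global optimum,
  so generating constants are recovered to ~1e-12 relative, and for noisy
  data it removes any dependence on a hand-picked start. Per-record absolute
  percentage errors, their mean and maximum are reported.
* **Linear-constant adjustment.** `adjust_linear_constant()` rescales only
  $k$ by the closed-form least-squares factor
  $\sum p_i o_i / \sum p_i^2$ between predictions and observations —
  exponents untouched — and reports the correction factor
  $k_{adj}/k_{sim}$. Observations may be supplied on the $Sh$ or the $k_L$
  scale; a common unit conversion cancels from the factor.

### Physical properties

* Kinematic viscosity: Vogel (VFT) equation over Kell (1975) density;
  $\nu(21.0\,°C) = 9.80\times10^{-7}\,\mathrm{m^2/s}$, within 0.25% of the
  $9.78\times10^{-7}$ used by the flow simulations this package
  post-processes.
* Oxygen diffusivity: linear in temperature, anchored so
  $D_{AB}(21.0\,°C) = 2.10\times10^{-9}\,\mathrm{m^2/s}$ exactly, slope
  $4.5\times10^{-11}\,\mathrm{m^2/s/°C}$ — the midpoint of the plausible
  literature band (≈2.1e-9 near 21 °C rising toward ≈2.8e-9 at 37 °C).
  Both coefficients are configurable and recorded in the run config.
* Oxygen solubility: Benson-Krause (1984) correlation (the USGS DO-table
  basis), scaled linearly in the oxygen partial pressure (Henry's law);
  default $p_{O_2} = 0.2095$ atm.

A note on internal consistency: with these defaults the Schmidt number at
21 °C is ≈466. The 366-395 interval quoted alongside the original fit range
is not reproducible from the stated 21 °C property pair (their ratio is
≈466), and the diffusivity fit behind it is not recoverable; the package
anchors on the explicitly stated property values and does not rescale
toward that interval. The synthetic Sherwood generator nevertheless samples
$Sc \in [366, 395]$ by default, because that is the stated coverage of the
fitted dataset it emulates.

### Cell-density bound

Equating oxygen transfer to uptake for a homogeneous culture that consumes
all transferred oxygen gives $X = k_La\,C_{sat}/q_{O_2}$
(`max_cell_density()`). With the literature $q_{O_2}$ bounds for pluripotent
stem cells ($1.00\times10^{-18}$ to $1.10\times10^{-16}$ mol/cell/s) the
bound spans exactly a factor 110 at fixed $k_La\,C_{sat}$.

## LES post-processing operators

All operators consume flat per-cell tables (position, cell volume, nine
velocity-gradient components, optional SGS kinetic energy), not solver case
directories. The filter width is $\Delta = V_{cell}^{1/3}$.

* Strain rate $\bar S_{ij} = \tfrac12(\partial_j \bar u_i + \partial_i \bar u_j)$.
* WALE eddy viscosity
  $\nu_t = (C_w\Delta)^2\,
   \frac{(S^d\!:\!S^d)^{3/2}}{(\bar S\!:\!\bar S)^{5/2} + (S^d\!:\!S^d)^{5/4}}$
  with $S^d$ the traceless symmetric part of the squared gradient and
  $C_w = 0.325$ (the usual solver default). The $0/0$ case returns 0. Two
  algebraic identities make sharp oracles: $\nu_t \equiv 0$ for pure shear
  (the squared gradient is nilpotent), and
  $\nu_t = (C_w\Delta)^2 (2/3)^{1/4}\omega$ for solid-body rotation at rate
  $\omega$ (the $\bar S = 0$ branch).
* Dissipation $\epsilon = 2\nu\,\bar S\!:\!\bar S + \epsilon_{SGS}$ with
  $\epsilon_{SGS} = C_\epsilon\,k_{SGS}^{3/2}/\Delta$, $C_\epsilon = 1.034$.
* Kolmogorov scale $\eta = (\nu^3/\epsilon)^{1/4}$, the hydrodynamic proxy
  for attainable aggregate size; $\epsilon = 0$ maps to `Inf` with a
  warning rather than an error.
* Shear stress: the product form $(\mu + \mu_t)\,\bar S\!:\!\bar S$ that
  appears in some post-processing scripts has units Pa/s, so the default is
  the dimensionally consistent magnitude
  $\tau = (\mu + \mu_t)\sqrt{2\,\bar S\!:\!\bar S}$; the literal product
  form stays available behind `literal = TRUE` for comparison.
* Turbulent diffusivity $D_{AB}^t = \nu_t / Sc_t$ with $Sc_t = 1.34$
  (transitional flow, high molecular Schmidt number).
* KE-resolution ratio $k_{ratio} = k_{res}/(k_{res} + k_{SGS})$ with
  $k_{res} = \tfrac12(\overline{u_x'^2}+\overline{u_y'^2}+\overline{u_z'^2})$;
  probes resolving less than 80% of the kinetic energy are flagged as
  under-resolved mesh. The sample set supplied per probe *is* the
  time-averaging window — the caller decides its length.
* Surface-flux $k_L = \langle N_{O_2}\rangle/(C_{sat} - \langle C_{O_2}\rangle)$
  with per-face $N_{O_2} = (D_{AB} + D_{AB}^t)\,|\partial C/\partial y|$
  (y is wall-normal into the bulk; fluxes are reported as magnitudes into
  the liquid). A vanished driving force ($< 10^{-9} C_{sat}$) is an error,
  not a division.
* Distribution summaries are volume-weighted by default (the alternative,
  cell-count weighting, over-represents refined regions); the volume
  fraction above $\epsilon = 0.5\times10^{-3}\,\mathrm{m^2/s^3}$ — a level
  relevant to stem-cell culture tolerance — is always reported.

## What the synthetic generators emulate — and what they do not

* `gen_luminescence()`: exponential-saturation intensity decay with
  additive Gaussian detector noise (default 1% of span), optional linear
  baseline drift applied uniformly across wavelengths, optional Gaussian
  emission spectra (sd 15 nm at 608 nm over a flat dark floor — only the
  peak position matters to the treatment). Defaults emulate a bench run:
  $k_La = 2\,\mathrm{h^{-1}}$ (mid experimental range), 4000-count span,
  five time constants of duration, ~150 samples. Not emulated:
  photobleaching, Stern-Volmer nonlinearity, non-Gaussian detector noise.
* `gen_flow()`: analytic Taylor-Green, solid-rotation, pure-shear and
  random smooth 2-D fields sampled at the cell centres of a uniform
  periodic grid, with closed-form dissipation and WALE values attached.
  Because cell-centre samples of $\sin^2$ over a full period average to
  exactly 1/2, the discrete Taylor-Green volume mean matches
  $\nu A^2 \kappa^2$ to machine precision; refinement tests therefore
  assert errors below the tolerance and non-increasing, rather than a
  fixed convergence ratio on exact zeros. Not emulated: wall-bounded
  turbulence, sliding-mesh artefacts, anything 3-D-inhomogeneous.
* `gen_sherwood_dataset()`: log-uniform group sampling over the stated fit
  ranges ($Re \in [624, 3172]$, $Sc \in [366, 395]$, $G \in [0.651, 1.08]$)
  with multiplicative Gaussian scatter on $Sh$ (relative scatter is the
  natural error structure of a fitted correlation, versus additive counts
  for a detector). Condition metadata defaults to the experimental
  temperature span 21.0-25.1 °C.
* `gen_surface_profile()`: film-theory construction in which every face
  receives the gradient $k_L (C_{sat}-C_{bulk})/D_{AB}$, optionally with
  zero-area-weighted-mean perturbations, so `surface_kl()` must return the
  constructed $k_L$ exactly.

Passing tests on these generators demonstrates correctness of the
*operators and fits*, not of the physics of a real reactor: real traces
have photophysics the generator omits, and real LES fields are not analytic.

## Problem sizes and determinism

The suite runs Taylor-Green oracles up to $64^3$ cells (the size at which
the discretisation argument above is exercised), 100-200 replicate seeds
for the noise-robustness summaries, and ~150-point traces — sizes chosen so
the whole suite completes in seconds while the Monte-Carlo medians are
stable to well under the asserted bounds. All stochastic paths take an
explicit integer seed; identical spec + seed gives bit-identical output.

## Known limitations

* The correlation was fitted for $624 \le Re \le 3172$; the package does not
  refuse extrapolation but the run report records the groups so users can
  check coverage.
* The plateau fallback in `fit_kla()` biases $k_La$ low on traces that lack
  a recorded pre-aeration plateau (see above); supply $I_{max}$, $I_{min}$
  when known.
* `ke_ratio()` treats the supplied samples as one stationary window; no
  windowing or detrending beyond mean removal is applied.
* Salinity/medium-composition corrections to the property correlations and
  gas-side resistance are out of scope (gas-side resistance is negligible
  for oxygen-water transfer).
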