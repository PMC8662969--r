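---
title: "Model-based analysis of specular reflectometry with specular"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based analysis of specular reflectometry with specular}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specular)
```

## The physical problem

Specular neutron and X-ray reflectometry measure the intensity `R(Q)` of
radiation reflected from a stratified interface as a function of momentum
transfer `Q = 4 pi sin(theta) / lambda` (1/Angstrom).  Nanometre-scale
films modulate `R(Q)` through interference, so a measured curve constrains
the depth profile of the scattering length density (sld) — the
number-density-weighted sum of atomic scattering lengths, in 1/Angstrom^2.
Because only intensities are measured, the phase information is lost and
the inversion is ill-posed; in practice the interface is modelled as a
stack of slabs whose parameters are refined against the data.

`specular` implements that workflow end to end: declarative multi-patch
slab models whose entries may be symbolic expressions in named parameters,
an Abelès transfer-matrix engine with Névot–Croce roughness, co-refinement
of several curves against one structural model by differential evolution,
and parameter uncertainty by Hessian curvature, bootstrap, or ensemble
MCMC.

## The forward model

For each patch the reflection amplitude is computed by multiplying the
2x2 characteristic matrices of its interfaces.  The normal wavevector in
layer `j` is

```
kz_j = sqrt((Q/2)^2 - 4 pi (rho_j - rho_0))
```

taken on the branch describing decaying transmitted/evanescent waves.  A
note on conventions: the user enters `rho = rho_re + i rho_im` with
`rho_im >= 0` meaning absorption; internally the engine works in the
`exp(-i omega t)` convention, where the argument of the square root is
`(Q/2)^2 - 4 pi (d_re - i d_im)`, so that its principal root has both
non-negative real and non-negative imaginary parts and reflectivities of
passive media never exceed one.  Each interfacial Fresnel coefficient is
damped by the Névot–Croce factor `exp(-2 kz_j kz_{j+1} sigma_j^2)`, where
`sigma_j` (Angstrom) is the Gaussian roughness of the interface between
layers `j` and `j + 1`.

Partially hydrated layers are mixed with solvent before the optical
calculation: `rho_wet = (1 - phi) rho_layer + phi rho_solv`, with `phi`
the solvent volume fraction.  The solvent sld is taken from the backing
medium by default (solid/liquid cells); `patch(..., solvent_from =
"fronting")` selects the fronting medium instead, which is the correct
geometry for air/liquid monolayers.  Patches contribute incoherently —
their reflectivities add, weighted by surface coverage — which is the
appropriate limit when lateral domains are much larger than the
instrument's coherence length.

Instrumental resolution is a Gaussian in `Q` whose width is either a
constant relative `dQ/Q` or a per-point `dQ` column (both FWHM;
`sigma = FWHM/2.35482`).  Smearing averages the unsmeared model over a
window of +/- 2.5 sigma with a 17-node Gauss–Legendre rule on a locally
refined grid; the truncated kernel is renormalised, so constants are
reproduced exactly and the quadrature agrees with a dense numerical
convolution of the same kernel to better than 1e-4 relative.  Scale and
background (`scale * R + background`) are applied last; since the
background is Q-independent, applying it after rather than before
smearing makes no difference.  `Q = 0` is rejected as input: the
kinematics are undefined there and measured files do not contain it.

## Symbolic model definition

Layer entries (sld, imaginary sld, thickness, roughness, solvent
fraction) are numbers or strings such as `"1 - (4*A/D^2)*(D*z - z^2)"`
over declared parameter names and the reserved layer index `n` (0 =
fronting).  Expressions are parsed once and evaluated in a sealed
environment exposing only arithmetic and standard mathematical functions
(trigonometric, `exp`, `log`, `log10`, `sqrt`, `abs`, `min`/`max`,
`erf`); anything else — including any form of code execution — is
rejected at construction time, and undeclared symbols are reported by
name.  Constraints between parameters are inequality strings over the
same vocabulary, e.g. the bilayer positivity conditions
`"1 - V/(apm*t) > 0"`.

Three builder families generate slab stacks for analytic profiles, all
sampling at slice mid-planes (second-order accurate) with zero
inter-slice roughness:

* `nanoparticle_layers()` — spheres of diameter `D`: particle volume
  fraction `phi(z) = (4 A / D^2)(D z - z^2)`, `A` defaulting to the
  close-packing fraction `pi/(2 sqrt(3)) ~ 0.91`.  Because `phi` depends
  only on `z/D`, the symbolic form stays valid while `A` and `D` are
  being fitted.  `nanoparticle_layers_polydisperse()` averages the
  profile over a normal diameter distribution (fixed 401-point trapezoid
  on +/- 4 sigma_D, truncated at positive diameters and renormalised — a
  deterministic rule that can be checked against Monte-Carlo
  integration).
* `brush_layers()` — end-grafted polymer brushes,
  `phi(z) = phi(0) (1 - (z/L)^n)`; mean-field theory gives `n = 2`
  (parabolic) at high grafting density.
* `bilayer_layers()` — four-region lipid bilayers (inner/outer heads and
  tails) from molecular scattering lengths `b`, volumes `V`, thicknesses
  `t` and the shared area per molecule `A_pm`.  The solvent fraction of a
  region is `1 - V/(A_pm t)`.  Its sld entry is the molecular sld `b/V`,
  chosen so that composition with the engine's volume-fraction mixing
  rule yields the volume-conserving hydrated sld
  `(b + (A_pm t - V) rho_solv)/(A_pm t)`; the dry part of the resolved
  layer equals the familiar `b/(A_pm t)`.  Symbolic `A_pm`/`t` entries
  emit the positivity constraints automatically.

`repeat_stack()` concatenates a unit cell `count` times for multilayers,
re-indexing any use of the layer symbol `n` so each copy sees local
indices.

With 100 slices the nanoparticle discretisation is converged to better
than 0.5% in `R(Q)` over this geometry's fitted range (up to
0.15 1/Angstrom, checked against a 400-slice reference); finer Q ranges
or thinner features may warrant more slices.

## Refinement

`refl_fit()` minimises one of four figures of merit over the free
parameters, each curve contributing `w_i / p_i * sum_j term_ij` (`p_i` =
number of points, so long curves do not dominate co-refinements):
linear or log10 scale, with or without experimental errors; the
log-with-errors variant uses the propagated uncertainty
`d(log10 R)^2 = [dR/(R ln 10)]^2`, and the linear no-error variant
weights by `1/R`.  The `1/R` denominator uses the experimental value so
the per-point weights are constant in the parameters and the objective
stays smooth.  Log modes drop non-positive data points (counted and
reported) and reject candidates whose model curve is non-positive.

The minimiser is a rand/1/bin differential evolution (population 15 per
dimension, `F = 0.7`, `CR = 0.9`, relative population-spread tolerance
1e-8, at most 2000 generations, fixed recorded seed): a global,
derivative-free search that copes with the multimodal landscapes typical
of reflectometry.  Candidates violating a constraint or resolving to
unphysical layers (negative thickness or roughness, solvent fraction
outside `[0, 1]`, non-finite entries) receive a large finite penalty
rather than `NaN`, so the search never crashes mid-stream; outside
fitting, `resolve_system()` treats the same conditions as hard errors.
Parameters declared with a normal prior are searched within
`mean +/- 5 sd` and add `((x - mean)/sd)^2` to the objective, which lets
the evolutionary search respect the prior without rejection sampling.
Per-curve scale, background and solvent slds are ordinary
(multi-)parameters, so any of them can be fixed or fitted per curve.

## Uncertainty estimation

Three estimators are provided, in increasing cost:

1. **Hessian** (`hessian_uncertainty()`): central finite differences with
   an adaptive, halving step estimate the diagonal curvature `H_kk` of
   the chi-squared at the optimum, and
   `sigma_k = sqrt(2 chi2_red_min / H_kk)` — the scaled-covariance
   convention, under which the estimate agrees with bootstrap and MCMC
   when residuals are consistent with `dR`.  Flat or ill-conditioned
   directions yield `NA` with a warning; the method is fast but the least
   robust.
2. **Bootstrap** (`bootstrap_fit()`, `K = 1000` by default): every curve
   is replicated by adding `Normal(0, dR)` noise point-wise and re-fitted
   independently; the sample mean and sd of each parameter are reported.
   Re-fits default to a reduced search box (best fit +/- 20% of each
   range) to bound runtime; `full_search = TRUE` restores the full
   bounds.
3. **Ensemble MCMC** (`mcmc_fit()`): Goodman–Weare stretch moves (affine
   invariant, so parameter rescalings are harmless) with
   `max(2 n_free + 2, 50)` walkers by default, a Gaussian likelihood
   `-1/2 sum[((R_e - R_m)/dR)^2 + ln(2 pi dR^2)]`, uniform-in-bounds or
   normal priors, and `-Inf` outside the constraints.  A 500-sample pilot
   chain estimates the integrated autocorrelation time `tau`
   (autocorrelation windowing with constant `c = 5`); `10 tau` samples
   are discarded as burn-in and production continues until at least
   `60 tau` retained steps, with a 50 000-step cap that raises an error
   suggesting bound revision.

`corner_stats()`/`plot_corner()` summarise posterior or bootstrap samples
(marginal histograms with the mean marked, pairwise 2D histograms,
Pearson correlations), and `confidence_band()` turns a thinned subset
(at least 200 draws) into point-wise central 68.27% envelopes of the
model curves and profiles — percentile bands without simultaneous-band
correction.

## Synthetic data and what the tests demonstrate

`generate_curve()` forward-calculates a model and perturbs it with
Gaussian noise `dR = relative_floor * R + 0.2 * background_level`: 1%
relative at the plateau by default, rising towards 20% where the signal
approaches the background, which mimics the counting statistics of
time-of-flight instruments and stresses the log-scale figures of merit
realistically.  `generate_contrast_series()` produces solvent
contrast-variation series sharing one structure.  The generator writes
the same `dR` it samples from, so error-weighted statistics are exactly
calibrated — which is what makes the package's statistical claims
testable: reduced chi-squared near one at the optimum, a half-normal
mean of `|R_noisy - R_model|/dR` near 0.798, and 68% posterior intervals
that cover the truth at close to the nominal rate.

The validation suite checks, among other things: the engine against an
independently written Parratt recursion (relative agreement better than
1e-10 on random 10-layer stacks) and against closed-form Fresnel and
Névot–Croce expressions; builder arithmetic against direct evaluation of
the analytic profiles; recovery of brush parameters
(`phi(0) = 0.10, L = 480, n = 2` under 2% noise) within 3 posterior sds;
recovery of the area per molecule of a three-contrast bilayer
co-refinement within 3 sds; pairwise agreement of the three uncertainty
estimators within a factor 1.5 on a single-layer problem; and posterior
coverage over 100 replications.  Problem sizes in the suite are kept
deliberately modest (25–100 points per curve, 50 brush slices, 6–10
MCMC walkers, bootstrap `K` of a few hundred) — enough for the
statistical assertions while keeping the whole suite quick on one CPU;
the same code scales to production-sized refinements unchanged.

Synthetic curves share the engine with the fitting path (only the noise
is external), so recovery tests demonstrate the *statistical* machinery
— identifiability, calibration, uncertainty — not the correctness of the
optics, which is instead established against the independent oracles
above.  Real data differ in ways the generator does not emulate:
correlated point-to-point errors, imperfect footprint correction,
non-Gaussian resolution tails, and model misspecification; passing the
suite therefore does not guarantee parameter accuracy on real
instruments, only that the estimator behaves correctly when the model is
true.

## Known limitations

* Spin-flip polarised reflectivity (a 4x4 formalism) is out of scope;
  non-spin-flip polarised pairs are handled by declaring the magnetic
  sld as a multi-parameter with `+rho_m`/`-rho_m` values per
  polarisation, which needs no engine change.
* Only Gaussian resolution kernels are supported.
* No gradient-based local polishing after differential evolution, and no
  free-form (spline) profiles — only the analytic families plus user
  expressions.
* The Hessian method reports marginal (diagonal) uncertainties only;
  strongly correlated parameters need bootstrap or MCMC.
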