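---
title: "Micron-scale specific energy and film response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micron-scale specific energy and film response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdosefilm)
```

## The problem

Absorbed dose D is a population average. In micrometre-sized targets at
millgray-level doses, the *specific energy* z — energy imparted per unit
mass in a single target — fluctuates wildly around D: many targets receive
no energy at all while a few receive multiples of D. `microdosefilm`
models this regime for radiochromic film, whose ~1 um monomer crystals act
as the sensitive volumes, and connects the specific-energy statistics to
the film's two readout modalities: net optical density (OD) measured with
a flatbed scanner at ~85 um resolution, and Raman spectroscopy (RS) of the
polymer bands at ~1 um resolution.

## The compound-Poisson specific-energy engine

The engine replaces voxel-scored Monte Carlo radiation transport with its
statistical skeleton. A voxel experiences `N ~ Poisson(lambda)`
energy-deposition events; each event deposits an i.i.d. single-event
specific energy `z1` with mean `mu1` and second raw moment `m2`, so

    z = z1(1) + ... + z1(N),     lambda = D / mu1.

The definition of `lambda` makes `E[z] = D` exact — the microdosimetric
identity that mean specific energy equals absorbed dose. Three closed
forms follow:

* zero-deposition fraction `f_{z=0} = exp(-lambda)`,
* microdosimetric spread `sigma_z / zbar = sqrt(m2 / (D * mu1))`,
  which scales as `1/sqrt(D)` at fixed target size,
* survival transform `E[exp(-alpha z)] = exp(-lambda (1 - M1(alpha)))`
  with `M1` the Laplace transform of the single-event spectrum.

Calibration inverts the first two: given a printed anchor
(`D`, `f_{z=0}`, spread), `calibrate_from_anchor()` solves
`lambda = -log(f_{z=0})`, `mu1 = D/lambda`,
`m2 = spread^2 * lambda * mu1^2`, and the model then reproduces the anchor
exactly and extrapolates to any dose via `lambda ~ D`.

```{r engine}
eng <- calibrate_from_anchor(0.003, 0.65, 3.43)  # small-voxel anchor
c(spread_0.03 = analytic_spread(eng, 0.03),
  f0_0.003 = zero_fraction(eng, 0.003))
```

Design choices made here, where several options were defensible:

* **Single-event family.** The default is a gamma spectrum: two free
  moments match any admissible `(mu1, m2)`, the Laplace transform is
  closed-form, and the heavy mass near zero mimics the short-chord /
  low-LET event spectrum. Delta, exponential, lognormal and empirical
  spectra are available; the lognormal transform is evaluated by adaptive
  quadrature at 1e-8 relative tolerance.
* **Mean chord length.** Computed as Cauchy's `4V/S` for the rectangular
  voxel — the standard convex-body convention.
* **Reproducibility.** A field is exactly reproducible from one integer
  seed at a fixed grid shape, using a single vectorized draw order.
  Counter-based per-voxel substreams were considered and rejected: base
  R's generator offers none, and reimplementing one would amount to a
  hand-rolled RNG.
* **Poisson counts are exact** (`rpois`), not a normal approximation, so
  the zero-fraction identity holds at any `lambda`. The delta family
  bypasses event materialization (`z = N * mu1`), which keeps
  high-`lambda` degenerate configurations cheap and exact.
* **Active-layer density** defaults to 1.2 g/cm^3 and is configurable.

Two dose grids are built in: `delivered_doses()` (the 15 delivered doses,
0.003–0.5 Gy) and `tabulated_doses()`, which differs in three low-dose
entries (0.006/0.009/0.011 vs 0.005/0.007/0.01); the irradiation plan
and the tabulated summaries disagree on these without explanation, so
both grids are provided and any dose vector is accepted. A related wrinkle: the tabulated large-voxel zero fraction at
0.006 Gy (0.099) is below pure Poisson scaling of the 0.003 Gy anchor
(0.35^2 = 0.1225). The engine is purely compound-Poisson and does not
model this; it is at the level of Monte Carlo noise in the tabulated
values.

## Field statistics

`summarize_field()` reports the mean, the *population* relative SD
(microdosimetric convention; at the 1e5–1e6 voxel counts used the
sample/population distinction is far below every tolerance in this
package), the exact zero-voxel fraction and the standard error of the
mean. `histogram_f()` keeps the point mass at z = 0 separate from a
binned density over z > 0 so that total mass is exactly 1; the default
200 log-spaced bins resolve distributions spanning several decades at low
dose. Spatial analyses mirror the measurement layout: the central
100 x 100 voxels of the mid-depth slice, sampled on a 10 x 10 grid of
evenly spaced rounded indices, normalized to the ROI mean.

## The one-hit detector model and its calibration

A sensitive volume is activated by a single hit; for specific energy z
the hit probability is `1 - exp(-alpha z)`, so the affected fraction at
dose D is

    R_theory(D) = 1 - Int exp(-alpha z) f(z; D) dz,

and each modality's signal is an affine transform of it:

    R(D) = m * R_theory(D) + c,

with scaling factor `m` and offset `c` (the film polymerizes slightly
even unirradiated, so `R(0) = c`). `response_integral()` evaluates the
integral against a histogram by midpoint quadrature;
`survival_transform()` is the closed-form counterpart used for
cross-checking. `fit_onehit()` estimates `(m, alpha, c)` by
Levenberg–Marquardt (via `minpack.lm`), with positivity of `m` and
`alpha` enforced by optimizing their logarithms; reported parameters are
on the natural scale. Defaults: unweighted least squares (weights
`1/sigma^2` optional when uncertainties are present), initialization
`c0 = response at the lowest dose`, `m0 = max(response) - c0`,
`alpha0 = 1 /Gy`; percentage differences use the measured value as
denominator. Calibration histograms default to the large-voxel geometry
(the monomer-crystal scale); small voxels are available as an option for
RS fits.

**Identifiability.** Over 0.003–0.5 Gy the response curve is only mildly
saturating, so `m` and `alpha` are strongly collinear (their product is
pinned by the low-dose slope, and only the curvature separates them).
Noise-free curves are recovered to four significant figures, but with
measurement noise of 2% of the maximum response the linearized relative
SD of `alpha` on the 15-dose design is ~31% (OD parameters) — a property
of the design, not the optimizer. Precise `alpha` estimation requires
either higher doses into saturation or strong priors; the test suite
documents this limit.

## Raman preprocessing chain

The chain runs despike → average repeats → SNIP baseline → vector
normalization → band ratio, per pixel:

* **Despiking.** Cosmic-ray removal routines are lab-specific and rarely
  published in detail; the implementation here is a documented
  median-replacement stand-in rather than a reimplementation of any
  particular one. Each reading is compared to its channel's median across the
  (>= 2) repeats; deviations beyond `threshold` (default 8) times the
  pooled median absolute deviation of the residual stack are replaced by
  the channel median, iterated to a fixpoint so the operation is
  idempotent. Pooling the scale across channels keeps the false-positive
  rate well under 1% with only 5 repeats, while single-channel outliers
  against otherwise identical repeats are still caught. The pooled scale
  assumes roughly uniform noise across channels.
* **SNIP** uses the log-log-square-root transform and a *decreasing*
  clipping window from `iterations` (default 40, i.e. a 160 cm^-1
  half-window at 4 cm^-1 sampling — wider than the broadest band) down
  to 1, which preserves peak shape. Known limitation: steep linear ramps
  are slightly clipped in transform space (residuals of a few percent);
  gentle smooth backgrounds are recovered to < 1%.
* **Band areas** are trapezoidal integrals over `center +/- width/2`
  with interpolated band edges. The dose-sensitive 1445 cm^-1 polymer
  band is ratioed to the dose-independent 2260 cm^-1 monomer band; the
  1445 integration width defaults to the same 14 cm^-1 stated for the
  reference band (its own width is not stated anywhere). The ratio is
  invariant to overall intensity drift, which is the point of internal
  standardization; vector normalization additionally stabilizes
  variance across sessions.
* An instrument sensitivity correction is supported only as an optional
  user-supplied per-channel multiplicative curve; no instrument model is
  included.

## OD maps and spread trends

`od_from_transmission()` implements `OD = log10(I0/I)`. "Averaging groups
of three adjacent pixels" is read as 3 x 3 block averaging (the stated
300 → 100 dpi reduction applies to both axes); a 1-D reading would not
halve the dpi claim consistently. By default transmissions are averaged
*before* the OD conversion, since the measurement chain averages pixels
first; the opposite order is available (`order = "od_first"`) because the
original order is unstated, and the two agree to high accuracy for smooth
images. The red channel is the default analysis channel.

Offset correction subtracts the 0 Gy signal. Two variants are provided:
`"pixelwise"` (default) subtracts the control *map*, so a map equal to
the control corrects to exactly zero; `"mean"` subtracts the scalar
control mean, matching a common description of the procedure. Either way
the corrected control has mean exactly 0. `power_law_fit()` fits
`rel SD = a * D^b` in log–log space; the pure compound-Poisson field has
`b = -1/2` exactly, and a dose-independent film-inhomogeneity floor in
the generator flattens the fitted exponent toward 0 monotonically —
the mechanism proposed for measured spreads sitting below the
microdosimetric expectation.

## What the synthetic generator does and does not emulate

`film_model()` + `synth_dose_series()` generate every input the chain
consumes: per-pixel specific energies from the engine, responses
`s * m * (1 - exp(-alpha z)) + c + noise` with lognormal per-pixel
sensitivity `s` (multiplicative on `m` only — crystal density varies
spatially, the offset chemistry does not), 16-bit transmission renderings
`I = I0 * 10^(-OD)` for OD, and full spectra (four dose-dependent bands
at 696/1086/1445/2060 cm^-1, fixed 2260 cm^-1 reference, smooth decaying
baseline, Gaussian noise, sparse cosmic spikes) for RS. Defaults follow
the fitted modality parameters (OD: 0.19 / 1.2 Gy^-1 / 0.026; RS: 8.6 /
1.02 Gy^-1 / 1.96), an RS sensitivity CV of 0.12 (inside the observed
8.9–17% pixel variation), OD noise of 0.003 OD units, OD sensitivity CV
of 0.05, and RS noise of 1% of the 1445 cm^-1 amplitude at 0.5 Gy; the
noise and inhomogeneity levels are free parameters chosen to resemble
observed scatter, stated here once and not tuned thereafter. An OD pixel
aggregates many voxels (default 100) reflecting the scanner's large
sampling area; an RS pixel is a single small voxel. Generated scans and
ROI sets carry their ground-truth `z` for validation.

The generator reproduces the *statistical structure* assumed by the
analysis: Poisson event counts, stationary single-event spectra,
multiplicative inhomogeneity, additive noise. It does not emulate
radiation transport (no energy spectrum, depth dose or scatter), scanner
lateral artifacts, spectrometer wavelength-dependent sensitivity, film
curl or scan-to-scan registration error. Passing tests therefore
establish internal consistency of the method chain under its own
assumptions, not fidelity to any particular scanner or spectrometer.

## Numerical choices and problem sizes

* Histogram mass conservation is exact by construction (counts/n); tests
  assert it to 1e-12.
* Histogram-vs-closed-form response integrals agree to 0.5% at
  `alpha <= 10 /Gy` with 200–300 log bins and >= 1e5 voxels.
* The Levenberg–Marquardt runs use `ftol = ptol = 1e-14`, 500 iteration
  cap; non-convergence is flagged on the returned object and warned.
* Degenerate inputs: all-zero fields report an undefined spread (flagged
  `NA`); single-valued positive fields widen their bin range by 1e-9;
  zero normalization references, non-increasing dose vectors, misaligned
  map shapes and out-of-axis bands are errors.
* Test and example sizes are chosen for desk-scale runs: 1e5–1e6 voxels
  for moment checks (3-standard-error bands), 100–400-pixel maps,
  10 x 10 x 5 spectra per ROI set, 200 replicate fits for the noise
  study.

## Known limitations

* `alpha` is weakly identified from mildly saturating dose ranges (see
  above); report `m * alpha` when only the low-dose slope matters.
* The engine's voxels are independent; real scored fields carry spatial
  correlation from electron tracks crossing voxel boundaries, so
  short-range spatial statistics of sampled maps are optimistic.
* SNIP under-recovers very steep smooth ramps by a few percent.
* The despike scale is pooled across channels and so assumes
  near-uniform noise; strongly heteroscedastic spectra would need a
  per-channel scale with more repeats.
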