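# microdosefilm

Micron-scale analysis of energy deposition and radiation response at low
dose (0.003–0.5 Gy), for medical physicists and radiation researchers
working with radiochromic film as a microdosimeter.

At millgray doses, energy deposition in micrometre-sized targets is
dominated by counting statistics: a voxel the size of a film monomer
crystal receives `N ~ Poisson(lambda)` energy-deposition events, each
depositing a random single-event specific energy `z1` with mean `mu1`
(Gy) and second moment `m2` (Gy²). The specific energy

    z = z1(1) + ... + z1(N),        lambda = D / mu1

has mean exactly the absorbed dose D, zero-deposition fraction
`f_{z=0} = exp(-lambda)`, and microdosimetric spread

    sigma_z / zbar = sqrt(m2 / (D * mu1))   (∝ 1/sqrt(D)).

The package provides:

* a **compound-Poisson engine** emulating Monte Carlo voxel scoring:
  calibrate a single-event model from printed summaries
  (`calibrate_from_anchor`), compute spreads, zero fractions and Laplace
  transforms analytically, and sample 3D specific-energy fields
  (`sample_field`);
* **microdosimetric statistics**: `summarize_field`, zero-spike-aware
  `f(z;D)` histograms (`histogram_f`), normalized spatial maps and
  10×10 grid sampling;
* the **one-hit detector model**: the affected-volume fraction
  `R_theory(D) = 1 − ∫ exp(−alpha·z) f(z;D) dz` and the modality
  response `R(D) = m·R_theory(D) + c`, with Levenberg–Marquardt
  calibration of `(m, alpha, c)` (`fit_onehit`);
* a **Raman preprocessing chain**: cosmic-ray despiking, repeat
  averaging, SNIP baseline estimation, vector normalization and
  internal-standard band ratios (1445 cm⁻¹ / 2260 cm⁻¹);
* **OD map analysis**: `OD = log10(I0/I)`, 3×3 block averaging, net OD
  maps, 0 Gy offset correction and power-law spread-vs-dose trends;
* a **synthetic-data generator** for both modalities (16-bit
  transmission scans, full Raman ROI sets) with configurable film
  inhomogeneity and noise;
* **I/O** for 3ddose voxel files, dose-response CSV, 16-bit TIFF/PNG
  scans, spectra stacks and YAML/JSON run configs, plus a thin CLI
  (`exec/microdose`).

## Worked example

Calibrate the engine from the small-voxel 0.003 Gy summary (65% of
voxels untouched, 343% spread), sample a field at 0.03 Gy, and fit the
one-hit model to a noise-free OD curve:

```r
library(microdosefilm)

engine <- calibrate_from_anchor(0.003, 0.65, 3.43)
engine
#> single-event model (gamma): mu1 = 0.006964 Gy, m2 = 0.0002458 Gy^2

field <- sample_field(engine, voxel_geometry_preset("vx-sm"), 0.03,
                      c(500, 500, 4), seed = 1)
summarize_field(field)
#> zbar = 0.02996 Gy (SE 3.3e-05), sigma_z/zbar = 1.086 (109%), f_{z=0} = 0.01342, n = 1000000

analytic_spread(engine, 0.03)                              # 1.085
analytic_spread(engine, 0.003) / analytic_spread(engine, 0.5)  # 12.9

# one-hit calibration on large-voxel histograms at the 15 study doses
eng_lg <- calibrate_from_anchor(0.003, 0.35, 2.05)
doses  <- delivered_doses()
set.seed(1)
hists <- lapply(doses, function(D)
  histogram_f(sample_field(eng_lg, voxel_geometry_preset("vx-lg"), D,
                           c(100, 100, 10))))
od <- vapply(hists, r_response, numeric(1), m = 0.19, alpha = 1.2, c = 0.026)
fit_onehit(dose_response_curve(doses, od, modality = "OD"), hists)
#> one-hit fit (OD): m = 0.19, alpha = 1.2 Gy^-1, c = 0.026
#>   max |percent difference| = 6.29e-14%, converged: TRUE
```

Reading the numbers: the sampled field's mean specific energy (0.030 Gy)
reproduces the nominal dose; its relative SD of 109% at 0.03 Gy follows
the `1/sqrt(D)` scaling from the 343% anchor; the spread at 3 mGy is
12.9× that at 0.5 Gy; and the fit recovers the generating parameters
`m = 0.19`, `alpha = 1.2 Gy⁻¹`, `c = 0.026` essentially exactly on a
noise-free curve.

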