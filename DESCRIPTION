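Package: microdosefilm
Title: Micron-Scale Specific-Energy Statistics and Radiochromic Film
    Dose Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Microdosimetric analysis of low-dose (0.003-0.5 Gy) photon
    irradiations of radiochromic film at micron scale. Provides a
    compound-Poisson specific-energy engine emulating Monte Carlo voxel
    scoring (single-event spectra, event frequencies, analytic moments,
    field sampling), microdosimetric summaries and spatial maps of
    specific-energy fields, the microdosimetric one-hit detector response
    model with Levenberg-Marquardt calibration, a Raman spectral
    preprocessing chain (cosmic-ray despiking, SNIP baseline estimation,
    vector and internal-standard normalization), optical-density map
    analysis with offset correction and power-law spread trends, a
    synthetic-data generator for both readout modalities, and readers and
    writers for 3ddose voxel files, dose-response tables, 16-bit scans
    and spectral stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
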