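#' 16-bit transmission scan container
#'
#' @param pixels Integer matrix of transmission readings in `[1, 65535]`
#'   (a zero reading has no defined OD and is rejected).
#' @param i0 White (unattenuated) level used to render the scan, if known.
#' @param channel Color channel label; the red channel is the analysis
#'   default for this dose range.
#' @param dpi Scan resolution (default 300).
#' @param dose Dose label (Gy).
#' @return An object of class `od_scan`.
#' @export
od_scan <- function(pixels, i0 = NA_real_, channel = "red", dpi = 300,
                    dose = NA_real_) {
  pixels <- as.matrix(pixels)
  if (any(pixels < 1) || any(pixels > 65535)) {
    stop("transmission readings must lie in [1, 65535]")
  }
  structure(list(pixels = pixels, i0 = i0, channel = channel, dpi = dpi,
                 dose = dose), class = "od_scan")
}

scan_pixels <- function(x) {
  if (inherits(x, "od_scan")) x$pixels else as.matrix(x)
}

#' @export
print.od_scan <- function(x, ...) {
  cat(sprintf(
    "OD scan: %d x %d px (%s channel, %g dpi), dose %.4g Gy\n",
    nrow(x$pixels), ncol(x$pixels), x$channel, x$dpi, x$dose
  ))
  invisible(x)
}

#' Film response model for the synthetic-data generator
#'
#' Parameterizes how a film pixel converts specific energy into signal:
#' `response = s * m * (1 - exp(-alpha * z)) + c + noise`, where `s` is a
#' lognormal per-pixel sensitivity (multiplicative on the scaling factor m
#' only: the offset arises chemistry-wide, while polymerizable-crystal
#' density varies spatially). Defaults reproduce the fitted response of each
#' modality: OD (m = 0.19, alpha = 1.2 Gy^-1, c = 0.026) and RS (m = 8.6,
#' alpha = 1.02 Gy^-1, c = 1.96).
#'
#' For RS, responses are rendered as full spectra: Gaussian dose-dependent
#' bands at 696, 1086, 1445 and 2060 cm^-1 whose amplitudes scale with the
#' pixel response, a dose-independent monomer reference band at 2260 cm^-1
#' (width 14 cm^-1), a smooth decaying baseline, additive Gaussian noise and
#' sparse cosmic-ray spikes. For OD, responses are rendered as 16-bit
#' transmission images via `I = I0 * 10^(-OD)`.
#'
#' @param modality `"OD"` or `"RS"`.
#' @param m,alpha,c One-hit response parameters (see above).
#' @param inhomogeneity_cv Coefficient of variation of the lognormal
#'   per-pixel sensitivity. Defaults: 0.12 (RS, matching the observed 8.9-17%
#'   pixel variation), 0.05 (OD).
#' @param noise_sd Additive measurement noise. Defaults: 0.003 OD units;
#'   for RS, 1% of the 1445 cm^-1 peak amplitude at 0.5 Gy (in counts).
#' @param i0 Scanner white level (OD only), default 60000.
#' @param peak_centers,peak_amplitudes Dose-dependent band centres (cm^-1)
#'   and their amplitudes (counts per unit response) relative to
#'   `amp_scale`.
#' @param ref_center,ref_amplitude Dose-independent internal-standard band.
#' @param band_fwhm Full width at half maximum of all bands (cm^-1).
#' @param amp_scale Counts per unit response for the 1445 cm^-1 band.
#' @param baseline_level,baseline_tau Baseline `level * exp(-(shift-min)/tau)`
#'   plus a constant floor of `level / 5`.
#' @param spike_rate Per-channel per-acquisition cosmic-ray probability.
#' @return An object of class `film_model`.
#' @export
film_model <- function(modality = c("OD", "RS"),
                       m = NULL, alpha = NULL, c = NULL,
                       inhomogeneity_cv = NULL, noise_sd = NULL,
                       i0 = 60000,
                       peak_centers = c(696, 1086, 1445, 2060),
                       peak_amplitudes = c(0.35, 0.55, 1, 0.6),
                       ref_center = 2260, ref_amplitude = 300,
                       band_fwhm = 14, amp_scale = 100,
                       baseline_level = 400, baseline_tau = 900,
                       spike_rate = 0.001) {
  modality <- match.arg(modality)
  if (is.null(m)) m <- if (modality == "OD") 0.19 else 8.6
  if (is.null(alpha)) alpha <- if (modality == "OD") 1.2 else 1.02
  if (is.null(c)) c <- if (modality == "OD") 0.026 else 1.96
  if (is.null(inhomogeneity_cv)) {
    inhomogeneity_cv <- if (modality == "OD") 0.05 else 0.12
  }
  if (is.null(noise_sd)) {
    noise_sd <- if (modality == "OD") 0.003
    else 0.01 * amp_scale * (m * (1 - exp(-alpha * 0.5)) + c)
  }
  if (m <= 0 || alpha <= 0) stop("m and alpha must be > 0")
  if (inhomogeneity_cv < 0) stop("inhomogeneity_cv must be >= 0")
  structure(list(
    modality = modality, m = m, alpha = alpha, c = c,
    inhomogeneity_cv = inhomogeneity_cv, noise_sd = noise_sd, i0 = i0,
    peak_centers = peak_centers, peak_amplitudes = peak_amplitudes,
    ref_center = ref_center, ref_amplitude = ref_amplitude,
    band_fwhm = band_fwhm, amp_scale = amp_scale,
    baseline_level = baseline_level, baseline_tau = baseline_tau,
    spike_rate = spike_rate
  ), class = "film_model")
}

# lognormal multiplicative sensitivities with unit mean and given CV
pixel_sensitivity <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# one-hit pixel response for a vector of pixel specific energies
pixel_response <- function(film, z, sens, noise = TRUE) {
  r <- sens * film$m * (1 - exp(-film$alpha * z)) + film$c
  if (noise && film$noise_sd > 0 && film$modality == "OD") {
    r <- r + stats::rnorm(length(z), 0, film$noise_sd)
  }
  r
}

#' Synthesize an OD transmission scan at one dose
#'
#' Each scan pixel aggregates many scoring voxels (the scanner pixel is tens
#' of micrometres, the voxels ~1 um): its specific energy is the mean of
#' `voxels_per_pixel` compound-Poisson voxel draws. The pixel response (net
#' OD above the control) follows the film model, and the transmission image
#' is rendered as `I = I0 * 10^(-OD)` quantized to 16-bit.
#'
#' @param dose Absorbed dose (Gy); 0 yields a control scan carrying only
#'   the offset signal and noise.
#' @param film A [film_model()] with modality `"OD"`.
#' @param engine A [single_event_model()].
#' @param geom A [voxel_geometry()].
#' @param pixels Integer `c(nx, ny)` scan dimensions (pre block averaging).
#' @param voxels_per_pixel Scoring voxels averaged per scan pixel.
#' @param seed Optional integer seed.
#' @return An [od_scan()] carrying, in element `z`, the generator-truth
#'   per-pixel specific energies (for validation).
#' @export
synth_od_scan <- function(dose, film, engine, geom, pixels = c(30, 30),
                          voxels_per_pixel = 100, seed = NULL) {
  stopifnot(inherits(film, "film_model"), film$modality == "OD")
  if (!is.null(seed)) set.seed(seed)
  n <- prod(pixels)
  fld <- sample_field(engine, geom, dose,
                      c(pixels[1], pixels[2], voxels_per_pixel))
  z <- apply(fld$values, c(1, 2), mean)
  sens <- matrix(pixel_sensitivity(n, film$inhomogeneity_cv),
                 pixels[1], pixels[2])
  od <- pixel_response(film, z, sens)
  i <- round(film$i0 * 10^(-od))
  i[i < 1] <- 1
  i[i > 65535] <- 65535
  out <- od_scan(i, i0 = film$i0, dose = dose)
  out$z <- z  # generator truth: per-pixel specific energy (Gy)
  out
}

# render one pixel's repeat spectra for the RS generator
render_rs_stack <- function(film, shifts, response, repeats) {
  sigma <- film$band_fwhm / (2 * sqrt(2 * log(2)))
  base <- film$baseline_level *
    exp(-(shifts - min(shifts)) / film$baseline_tau) +
    film$baseline_level / 5
  peaks <- rowSums(vapply(seq_along(film$peak_centers), function(k) {
    film$amp_scale * film$peak_amplitudes[k] * response *
      exp(-(shifts - film$peak_centers[k])^2 / (2 * sigma^2))
  }, numeric(length(shifts))))
  refpk <- film$ref_amplitude *
    exp(-(shifts - film$ref_center)^2 / (2 * sigma^2))
  clean <- base + peaks + refpk
  nchan <- length(shifts)
  st <- matrix(clean, nchan, repeats) +
    matrix(stats::rnorm(nchan * repeats, 0, film$noise_sd), nchan, repeats)
  if (film$spike_rate > 0) {
    hit <- stats::runif(nchan * repeats) < film$spike_rate
    if (any(hit)) {
      st[hit] <- st[hit] + stats::runif(sum(hit), 10, 40) *
        max(film$noise_sd, 1) * 10
    }
  }
  st
}

#' Synthesize a Raman ROI set at one dose
#'
#' Per pixel, a single small-voxel specific energy z is drawn (the Raman
#' sampling volume matches one voxel), converted to a response via the film
#' model, and rendered as `repeats` spectra with baseline, noise and cosmic
#' spikes. The 2260 cm^-1 band is dose-independent by construction.
#'
#' @inheritParams synth_od_scan
#' @param film A [film_model()] with modality `"RS"`.
#' @param grid Integer `c(nx, ny)` pixel grid (default 10 x 10).
#' @param repeats Acquisitions per pixel (default 5).
#' @param shifts Raman axis (default [raman_axis()]).
#' @return A [raman_roiset()] carrying generator truth in elements `z`
#'   (per-pixel specific energies) and `response_truth`.
#' @export
synth_raman_roiset <- function(dose, film, engine, geom, grid = c(10, 10),
                               repeats = 5, shifts = raman_axis(),
                               seed = NULL) {
  stopifnot(inherits(film, "film_model"), film$modality == "RS")
  if (!is.null(seed)) set.seed(seed)
  npix <- prod(grid)
  fld <- sample_field(engine, geom, dose, c(grid[1], grid[2], 1))
  z <- as.numeric(fld$values)
  sens <- pixel_sensitivity(npix, film$inhomogeneity_cv)
  resp <- pixel_response(film, z, sens, noise = FALSE)
  cube <- array(0, dim = c(length(shifts), repeats, npix))
  for (p in seq_len(npix)) {
    cube[, , p] <- render_rs_stack(film, shifts, resp[p], repeats)
  }
  out <- raman_roiset(shifts, cube, grid_dim = grid, dose = dose)
  out$z <- z          # generator truth: per-pixel specific energy (Gy)
  out$response_truth <- resp
  out
}

#' Synthesize a full dose series with 0 Gy control
#'
#' Generates, for every dose in `doses` plus an unirradiated control, the
#' dataset the analysis chain consumes: a specific-energy field and either
#' an OD transmission scan or a Raman ROI set depending on the film
#' modality. Fully reproducible from `seed`.
#'
#' @param doses Doses (Gy), strictly positive (the 0 Gy control is added
#'   automatically).
#' @inheritParams synth_od_scan
#' @param ... Passed to [synth_od_scan()] or [synth_raman_roiset()].
#' @return List with `doses`, `control` and `datasets` (one per dose); each
#'   dataset holds `dose`, `field` and `scan` (OD) or `roiset` (RS).
#' @export
synth_dose_series <- function(doses, film, engine, geom, seed = 1, ...) {
  stopifnot(inherits(film, "film_model"))
  if (any(doses <= 0)) stop("doses must be > 0 (control is added)")
  set.seed(seed)
  gen1 <- function(D) {
    fld <- sample_field(engine, geom, max(D, 0), c(32, 32, 2))
    ds <- list(dose = D, field = fld)
    if (film$modality == "OD") {
      ds$scan <- synth_od_scan(D, film, engine, geom, ...)
    } else {
      ds$roiset <- synth_raman_roiset(D, film, engine, geom, ...)
    }
    ds
  }
  list(doses = doses, control = gen1(0),
       datasets = lapply(doses, gen1))
}

#' Inject an offset signal into a dataset
#'
#' Adds a constant response offset, emulating the intrinsic 0 Gy signal
#' from initial polymerization. For a [dose_response_curve()] the offset is
#' added to every response; for an [od_scan()] the transmissions are
#' attenuated by `10^(-c)` so the rendered net OD gains `c`. Downstream
#' [offset_correct()] must null it.
#'
#' @param dataset A [dose_response_curve()] or [od_scan()].
#' @param c Offset in response units (net OD for scans).
#' @return The dataset with the offset applied.
#' @export
inject_offset_signal <- function(dataset, c) {
  if (inherits(dataset, "dose_response_curve")) {
    dataset$responses <- dataset$responses + c
    return(dataset)
  }
  if (inherits(dataset, "od_scan")) {
    px <- round(dataset$pixels * 10^(-c))
    px[px < 1] <- 1
    px[px > 65535] <- 65535
    dataset$pixels <- px
    return(dataset)
  }
  stop("inject_offset_signal supports dose_response_curve and od_scan")
}
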