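#' Raman shift axis
#'
#' Default measurement axis: 614-2313 cm^-1 sampled every 4 cm^-1
#' (425 channels, last channel 2310 cm^-1).
#'
#' @param from,to Axis limits (cm^-1); channels above `to` are dropped.
#' @param by Spectral resolution (cm^-1).
#' @return Strictly increasing numeric vector of Raman shifts.
#' @export
raman_axis <- function(from = 614, to = 2313, by = 4) {
  seq(from, to, by = by)
}

#' Remove cosmic-ray spikes from repeat spectra
#'
#' Cosmic-ray events hit single channels of single acquisitions with
#' intensities far above the Raman signal. With >= 2 repeat acquisitions per
#' pixel, each reading is compared to its channel's median across repeats;
#' readings deviating by more than `threshold` times the robust deviation
#' scale are replaced by the channel median. The scale is the median
#' absolute deviation of the whole residual stack (readings minus their
#' channel medians): pooling makes it insensitive both to the handful of
#' spikes and to the instability of per-channel estimates from few repeats.
#' Clean spectra pass through unchanged.
#'
#' @param stack Numeric matrix, channels x repeats.
#' @param threshold Multiple of the robust deviation scale above which a
#'   reading is a spike (default 8).
#' @return Matrix of the same shape with spikes replaced.
#' @export
despike <- function(stack, threshold = 8) {
  stack <- as.matrix(stack)
  if (ncol(stack) < 2) {
    warning("single repeat: despiking skipped (pass-through)")
    return(stack)
  }
  # iterate replacement to a fixpoint so despiking is idempotent even
  # though the pooled scale shrinks slightly once spikes are removed
  for (pass in 1:10) {
    med <- apply(stack, 1, stats::median)
    dev <- abs(stack - med)
    lim <- threshold * stats::median(dev)
    spikes <- dev > lim
    if (!any(spikes)) break
    stack[spikes] <- med[row(stack)[spikes]]
  }
  stack
}

#' Average repeat spectra into one representative spectrum per pixel
#'
#' Channel-wise mean of the (despiked) repeat acquisitions; with k i.i.d.
#' noisy repeats the noise SD drops by sqrt(k).
#'
#' @param stack Numeric matrix, channels x repeats.
#' @return Numeric vector of channel means.
#' @export
pixel_average <- function(stack) {
  stack <- as.matrix(stack)
  if (ncol(stack) < 1) stop("need at least one repeat")
  rowMeans(stack)
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive nonlinear iterative peak clipping. Intensities are
#' mapped through the log-log-square-root (LLS) operator to compress dynamic
#' range, then each channel is iteratively clipped to the minimum of itself
#' and the mean of its neighbours at distance k, with the window k decreasing
#' from `iterations` down to 1 (the decreasing-window variant, which
#' preserves peak shape), and finally mapped back. The default of 40
#' iterations corresponds to a 160 cm^-1 half-window at 4 cm^-1 sampling,
#' wider than the broadest Raman band of the film.
#'
#' @param intensities Numeric spectrum (counts).
#' @param iterations Maximum clipping half-window in channels (>= 1).
#' @return List with `baseline` and `corrected` (= intensities - baseline;
#'   non-negative up to floating-point rounding wherever intensities are).
#' @export
snip_baseline <- function(intensities, iterations = 40) {
  n <- length(intensities)
  if (iterations < 1) stop("iterations must be >= 1")
  if (n < 2 * iterations + 1) {
    stop("spectrum too short: need length >= 2*iterations + 1")
  }
  y0 <- pmax(intensities, 0)
  v <- log(log(sqrt(y0 + 1) + 1) + 1)
  for (k in seq(iterations, 1)) {
    i <- (k + 1):(n - k)
    v[i] <- pmin(v[i], (v[i - k] + v[i + k]) / 2)
  }
  baseline <- (exp(exp(v) - 1) - 1)^2 - 1
  list(baseline = baseline, corrected = intensities - baseline)
}

#' Vector (Euclidean) normalization of a spectrum
#'
#' Scales intensities to unit Euclidean norm, removing overall intensity
#' differences (laser power, focus) between measurement sessions.
#'
#' @param intensities Numeric spectrum.
#' @return Spectrum with `sqrt(sum(x^2)) = 1`.
#' @export
vector_normalize <- function(intensities) {
  nrm <- sqrt(sum(intensities^2))
  if (nrm == 0) stop("cannot normalize an all-zero spectrum")
  intensities / nrm
}

#' Area under a spectral band
#'
#' Trapezoidal integral of intensity over `[center - width/2,
#' center + width/2]`, with linear interpolation at the band edges so the
#' integration window is exact even when edges fall between channels.
#'
#' @param shifts Strictly increasing Raman-shift axis (cm^-1).
#' @param intensities Intensities, same length as `shifts`.
#' @param center Band centre (cm^-1).
#' @param width Band width (cm^-1), default 14 (the internal-standard
#'   monomer band convention).
#' @return Band area (intensity x cm^-1).
#' @export
band_area <- function(shifts, intensities, center, width = 14) {
  if (length(shifts) != length(intensities)) {
    stop("shifts and intensities must have equal length")
  }
  lo <- center - width / 2
  hi <- center + width / 2
  if (lo < min(shifts) || hi > max(shifts)) {
    stop(sprintf("band [%.6g, %.6g] cm^-1 lies outside the spectral axis",
                 lo, hi))
  }
  inside <- shifts > lo & shifts < hi
  x <- c(lo, shifts[inside], hi)
  y <- c(stats::approx(shifts, intensities, lo)$y,
         intensities[inside],
         stats::approx(shifts, intensities, hi)$y)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Raman ROI set
#'
#' Spectra acquired on a pixel grid over a region of interest, with repeat
#' acquisitions per pixel: by default a 10 x 10 grid over 100 x 100 um with
#' 5 repeats (500 spectra per sample).
#'
#' @param shifts Raman-shift axis (cm^-1).
#' @param cube 3D array channels x repeats x pixels (pixels in column-major
#'   grid order).
#' @param grid_dim Integer `c(nx, ny)` pixel-grid dimensions.
#' @param dose Dose label (Gy).
#' @return An object of class `raman_roiset`.
#' @export
raman_roiset <- function(shifts, cube, grid_dim = c(10, 10),
                         dose = NA_real_) {
  stopifnot(length(dim(cube)) == 3L, dim(cube)[1] == length(shifts),
            dim(cube)[3] == prod(grid_dim))
  if (is.unsorted(shifts, strictly = TRUE)) {
    stop("shifts must be strictly increasing")
  }
  structure(list(shifts = shifts, cube = cube,
                 grid_dim = as.integer(grid_dim), dose = dose),
            class = "raman_roiset")
}

#' @export
print.raman_roiset <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf(
    "Raman ROI set: %d x %d grid, %d repeats, %d channels, dose %.4g Gy\n",
    x$grid_dim[1], x$grid_dim[2], d[2], d[1], x$dose
  ))
  invisible(x)
}

#' Preprocess one ROI set into per-pixel response values
#'
#' Runs the measurement chain per pixel: despike across repeats, average the
#' repeats, SNIP-subtract the baseline, vector-normalize, then take the ratio
#' of the dose-sensitive band area (1445 cm^-1 polymer band) to the
#' dose-independent internal-standard band area (2260 cm^-1 monomer band).
#' An optional per-channel multiplicative instrument-response correction
#' (e.g. from a fluorescence standard) is applied before baseline removal.
#'
#' @param roiset A [raman_roiset()].
#' @param response_center Dose-sensitive band centre (cm^-1), default 1445.
#' @param ref_center Internal-standard band centre (cm^-1), default 2260.
#' @param width Band width for both integrations (cm^-1), default 14.
#' @param snip_iterations Passed to [snip_baseline()].
#' @param despike_threshold Passed to [despike()].
#' @param correction Optional per-channel multiplicative correction curve.
#' @return A [spatial_map()] of per-pixel normalized responses.
#' @export
rs_pixel_map <- function(roiset, response_center = 1445, ref_center = 2260,
                         width = 14, snip_iterations = 40,
                         despike_threshold = 8, correction = NULL) {
  stopifnot(inherits(roiset, "raman_roiset"))
  if (!is.null(correction) &&
      length(correction) != length(roiset$shifts)) {
    stop("correction curve must have one value per channel")
  }
  npix <- dim(roiset$cube)[3]
  ratio <- vapply(seq_len(npix), function(p) {
    st <- despike(roiset$cube[, , p], threshold = despike_threshold)
    sp <- pixel_average(st)
    if (!is.null(correction)) sp <- sp * correction
    sp <- snip_baseline(sp, iterations = snip_iterations)$corrected
    sp <- vector_normalize(sp)
    band_area(roiset$shifts, sp, response_center, width) /
      band_area(roiset$shifts, sp, ref_center, width)
  }, numeric(1))
  spatial_map(matrix(ratio, roiset$grid_dim[1], roiset$grid_dim[2]))
}

#' Raman dose response across a dose series
#'
#' Applies [rs_pixel_map()] to each ROI set and summarizes the ROI: the mean
#' normalized 1445/2260 response per dose forms the dose-response curve, and
#' the per-pixel relative SD quantifies micron-scale heterogeneity. Being a
#' ratio of band areas, the response is invariant to overall intensity drift.
#'
#' @param roisets List of [raman_roiset()]s, one per dose, in increasing
#'   dose order (dose labels are read from the sets).
#' @param offset_control Optional 0 Gy [raman_roiset()]; when supplied, its
#'   pixel map is subtracted pixel-by-pixel from each dose map before
#'   summarizing (offset-signal correction).
#' @inheritParams rs_pixel_map
#' @return List with `curve` (a [dose_response_curve()], modality RS),
#'   `maps` (per-dose [spatial_map()]s), `relative_sd` (per-dose fraction).
#' @export
rs_dose_response <- function(roisets, offset_control = NULL, ...) {
  doses <- vapply(roisets, function(r) r$dose, numeric(1))
  if (any(is.na(doses))) stop("every ROI set needs a dose label")
  maps <- lapply(roisets, rs_pixel_map, ...)
  if (!is.null(offset_control)) {
    if (!inherits(offset_control, "raman_roiset")) {
      stop("offset correction requested but no control ROI set supplied")
    }
    ctrl <- rs_pixel_map(offset_control, ...)
    maps <- lapply(maps, offset_correct, control = ctrl)
  }
  means <- vapply(maps, function(m) mean(m$values), numeric(1))
  sds <- vapply(maps, function(m) stats::sd(as.numeric(m$values)),
                numeric(1))
  list(
    curve = dose_response_curve(doses, means, modality = "RS"),
    maps = maps,
    relative_sd = sds / abs(means)
  )
}
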