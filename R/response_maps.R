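#' Optical density from transmission readings
#'
#' `OD = log10(I0 / I)` with I0 the control (unirradiated) and I the
#' irradiated transmission reading. Additive under multiplicative
#' attenuation.
#'
#' @param i0,i Positive transmission readings (scanner pixel values).
#'   Vectorized.
#' @return Optical density (dimensionless).
#' @export
od_from_transmission <- function(i0, i) {
  if (any(i0 <= 0) || any(i <= 0)) {
    stop("transmission readings must be > 0")
  }
  log10(i0 / i)
}

#' Non-overlapping block averaging of an image
#'
#' Averages `factor` x `factor` pixel blocks, e.g. reducing a 300 dpi scan
#' to 100 dpi with `factor = 3` and suppressing uncorrelated noise by the
#' block size (SD / factor). Trailing rows/columns that do not fill a block
#' are cropped.
#'
#' @param image Numeric matrix.
#' @param factor Block edge length in pixels (default 3).
#' @return Matrix of block means, dims `floor(dim/factor)`.
#' @export
block_average <- function(image, factor = 3) {
  image <- as.matrix(image)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(image)
  nr <- nrow(image) %/% factor * factor
  nc <- ncol(image) %/% factor * factor
  if (nr < factor || nc < factor) stop("image smaller than one block")
  x <- image[seq_len(nr), seq_len(nc), drop = FALSE]
  gi <- (seq_len(nr) - 1L) %/% factor
  gj <- (seq_len(nc) - 1L) %/% factor
  s <- rowsum(x, gi, reorder = TRUE)
  s <- t(rowsum(t(s), gj, reorder = TRUE))
  unname(s / factor^2)
}

#' Net optical density map from a scan pair
#'
#' Computes the pixel-wise net OD `log10(control / irradiated)`. By default
#' transmissions are block-averaged first and OD taken afterwards
#' (`order = "average_first"`); `order = "od_first"` converts per pixel and
#' averages ODs instead.
#'
#' @param scan,control_scan [od_scan()]s (or plain matrices) of the
#'   irradiated and control films, aligned and equal in shape.
#' @param factor Block-averaging factor (default 3; 300 -> 100 dpi).
#' @param order Whether to average transmissions before or after the OD
#'   conversion.
#' @return A [spatial_map()] of net OD; pitch derived from the scan dpi
#'   when available.
#' @export
net_od_map <- function(scan, control_scan, factor = 3,
                       order = c("average_first", "od_first")) {
  order <- match.arg(order)
  a <- scan_pixels(scan)
  b <- scan_pixels(control_scan)
  if (!all(dim(a) == dim(b))) stop("scan and control shapes differ")
  if (any(a <= 0) || any(b <= 0)) stop("transmission readings must be > 0")
  v <- if (order == "average_first") {
    log10(block_average(b, factor) / block_average(a, factor))
  } else {
    block_average(log10(b / a), factor)
  }
  pitch <- NA_real_
  if (inherits(scan, "od_scan") && is.finite(scan$dpi)) {
    pitch <- 25400 / scan$dpi * factor  # um per averaged pixel
  }
  spatial_map(v, pitch = pitch)
}

#' Offset-signal correction of response maps
#'
#' The film shows a response at 0 Gy from initial polymerization; this
#' offset masks the dose-dependent spread at low doses. The correction
#' subtracts the unirradiated (0 Gy) signal: `method = "pixelwise"` (default)
#' subtracts the control map pixel by pixel; `method = "mean"` subtracts the
#' scalar control-map mean everywhere. Either way the corrected control map
#' has mean exactly 0.
#'
#' @param map2d Response [spatial_map()] (or matrix) at dose D.
#' @param control Control [spatial_map()] (or matrix) at 0 Gy, same shape.
#' @param method Correction variant; see Details.
#' @return Corrected [spatial_map()].
#' @export
offset_correct <- function(map2d, control,
                           method = c("pixelwise", "mean")) {
  method <- match.arg(method)
  v <- map_values(map2d)
  cv <- map_values(control)
  if (!all(dim(v) == dim(cv))) stop("map and control shapes differ")
  out <- if (method == "pixelwise") v - cv else v - mean(cv)
  pitch <- if (inherits(map2d, "spatial_map")) map2d$pitch else NA_real_
  spatial_map(out, pitch = pitch)
}

#' Power-law trend of relative spread versus dose
#'
#' Fits `relative_sd = a * D^b` by linear least squares in log-log space.
#' The pure compound-Poisson field has exponent b = -0.5 exactly; film
#' inhomogeneity adds a dose-independent floor that flattens the fitted
#' exponent toward 0.
#'
#' @param doses Doses (Gy); only strictly positive points are fitted.
#' @param relative_sds Relative standard deviations (fractions or %);
#'   only strictly positive points are fitted.
#' @return An object of class `trend_fit`: `amplitude`, `exponent`,
#'   `r_squared`, `n_used`.
#' @export
power_law_fit <- function(doses, relative_sds) {
  if (length(doses) != length(relative_sds)) {
    stop("doses and relative_sds must have equal length")
  }
  ok <- is.finite(doses) & is.finite(relative_sds) &
    doses > 0 & relative_sds > 0
  if (sum(ok) < 2) stop("need at least 2 positive points")
  fit <- stats::lm(log(relative_sds[ok]) ~ log(doses[ok]))
  ly <- log(relative_sds[ok])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((ly - mean(ly))^2)
  structure(list(
    amplitude = exp(unname(stats::coef(fit)[1])),
    exponent = unname(stats::coef(fit)[2]),
    r_squared = if (tss > 0) 1 - rss / tss else 1,
    n_used = sum(ok)
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "power-law trend: rel SD = %.4g * D^%.4g (R^2 = %.4g, n = %d)\n",
    x$amplitude, x$exponent, x$r_squared, x$n_used
  ))
  invisible(x)
}

#' Relative-SD summary of a map
#'
#' @param map2d A [spatial_map()] or matrix.
#' @return List with `mean`, `sd` and `relative_sd` (sd / |mean|).
#' @export
map_stats <- function(map2d) {
  v <- as.numeric(map_values(map2d))
  list(mean = mean(v), sd = stats::sd(v),
       relative_sd = stats::sd(v) / abs(mean(v)))
}
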