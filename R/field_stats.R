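#' Microdosimetric summary of a specific-energy field
#'
#' Computes the Table-1-style quantities: mean specific energy zbar (the
#' realized dose), relative standard deviation sigma_z/zbar (population SD,
#' the microdosimetric convention), the exact fraction of voxels with z = 0,
#' and the standard error of the mean.
#'
#' @param field A [specific_energy_field()] or numeric array.
#' @return An object of class `microdose_summary`: list with `dose`,
#'   `spread` (fraction; `NA` with a `spread_defined = FALSE` flag for an
#'   all-zero field), `zero_fraction`, `n_voxels`, `se_mean`.
#' @export
summarize_field <- function(field) {
  z <- field_values(field)
  n <- length(z)
  if (n == 0) stop("empty field")
  mu <- mean(z)
  sd_pop <- sqrt(mean((z - mu)^2))
  spread_defined <- mu > 0
  structure(list(
    dose = mu,
    spread = if (spread_defined) sd_pop / mu else NA_real_,
    spread_defined = spread_defined,
    zero_fraction = mean(z == 0),
    n_voxels = n,
    se_mean = sd_pop / sqrt(n)
  ), class = "microdose_summary")
}

#' @export
print.microdose_summary <- function(x, ...) {
  cat(sprintf(
    "zbar = %.4g Gy (SE %.2g), sigma_z/zbar = %s, f_{z=0} = %.4g, n = %d\n",
    x$dose, x$se_mean,
    if (x$spread_defined) sprintf("%.4g (%.3g%%)", x$spread, 100 * x$spread)
    else "undefined (all-zero field)",
    x$zero_fraction, x$n_voxels
  ))
  invisible(x)
}

field_values <- function(field) {
  if (inherits(field, "specific_energy_field")) as.numeric(field$values)
  else as.numeric(field)
}

#' Specific-energy histogram f(z; D)
#'
#' Separates the point mass at z = 0 from a binned density over z > 0 so
#' that the total probability mass (zero spike plus integral of the density)
#' is exactly 1. Log-spaced bins (the default) resolve distributions that
#' span decades at low dose; linear bins span \code{[0, max z]}.
#'
#' @param field A [specific_energy_field()] or numeric array of z values.
#' @param n_bins Number of bins for z > 0 (default 200).
#' @param binning `"log"` or `"linear"`.
#' @return An object of class `se_histogram`: `zero_mass`, `bin_edges`
#'   (length `n_bins + 1`, Gy), `densities` (per Gy), `n`.
#' @export
histogram_f <- function(field, n_bins = 200, binning = c("log", "linear")) {
  binning <- match.arg(binning)
  if (n_bins < 1) stop("n_bins must be >= 1")
  z <- field_values(field)
  n <- length(z)
  if (n == 0) stop("empty field")
  if (any(z < 0)) stop("specific energies must be >= 0")
  zero_mass <- mean(z == 0)
  pos <- z[z > 0]
  if (length(pos) == 0) {
    return(structure(list(zero_mass = 1, bin_edges = numeric(0),
                          densities = numeric(0), n = n),
                     class = "se_histogram"))
  }
  lo <- min(pos)
  hi <- max(pos)
  if (lo == hi) {  # degenerate: widen symmetrically
    lo <- lo * (1 - 1e-9)
    hi <- hi * (1 + 1e-9)
  }
  edges <- if (binning == "log") {
    exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  } else {
    seq(0, hi, length.out = n_bins + 1)
  }
  idx <- findInterval(pos, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  widths <- diff(edges)
  structure(list(zero_mass = zero_mass, bin_edges = edges,
                 densities = counts / (n * widths), n = n),
            class = "se_histogram")
}

#' Construct a histogram directly (e.g. the degenerate zero-dose one)
#'
#' @param zero_mass Point mass at z = 0 in \code{[0, 1]}.
#' @param bin_edges,densities Binned density over z > 0; must integrate to
#'   `1 - zero_mass`.
#' @return An `se_histogram`.
#' @export
se_histogram <- function(zero_mass, bin_edges = numeric(0),
                         densities = numeric(0)) {
  h <- structure(list(zero_mass = zero_mass, bin_edges = bin_edges,
                      densities = densities, n = NA_integer_),
                 class = "se_histogram")
  if (abs(histogram_mass(h) - 1) > 1e-8) {
    stop("histogram mass (zero spike + integral) must equal 1")
  }
  h
}

#' Total probability mass and mean of an se_histogram
#' @param hist An `se_histogram`.
#' @return `histogram_mass`: the total mass (1 up to rounding);
#'   `histogram_mean`: the mean specific energy implied by the histogram.
#' @export
histogram_mass <- function(hist) {
  hist$zero_mass + sum(hist$densities * diff(hist$bin_edges))
}

#' @rdname histogram_mass
#' @export
histogram_mean <- function(hist) {
  if (length(hist$densities) == 0) return(0)
  mids <- (utils::head(hist$bin_edges, -1) + utils::tail(hist$bin_edges, -1)) / 2
  sum(mids * hist$densities * diff(hist$bin_edges))
}

#' @export
print.se_histogram <- function(x, ...) {
  cat(sprintf("f(z;D) histogram: zero mass %.4g, %d bins, mean %.4g Gy\n",
              x$zero_mass, length(x$densities), histogram_mean(x)))
  invisible(x)
}

#' 2D spatial map container
#'
#' @param values Numeric matrix.
#' @param pitch Pixel pitch in micrometres (optional).
#' @param reference Normalization reference recorded by [normalize_map()].
#' @return An object of class `spatial_map`.
#' @export
spatial_map <- function(values, pitch = NA_real_, reference = NA_real_) {
  structure(list(values = as.matrix(values), pitch = pitch,
                 reference = reference), class = "spatial_map")
}

map_values <- function(m) {
  if (inherits(m, "spatial_map")) m$values else as.matrix(m)
}

#' @export
print.spatial_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("spatial map %d x %d: mean %.4g, SD %.4g", nrow(v), ncol(v),
              mean(v), stats::sd(as.numeric(v))))
  if (!is.na(x$pitch)) cat(sprintf(", pitch %.4g um", x$pitch))
  cat("\n")
  invisible(x)
}

#' Sample a coarse grid from a 2D map
#'
#' Picks `nx` x `ny` pixels at evenly spaced (rounded) indices across the
#' source map, emulating a Raman stage rastering a 10 x 10 grid over the
#' central region of interest.
#'
#' @param map2d Matrix or [spatial_map()].
#' @param nx,ny Output grid dimensions (default 10 x 10).
#' @return A [spatial_map()] of shape `nx` x `ny`.
#' @export
grid_sample <- function(map2d, nx = 10, ny = 10) {
  v <- map_values(map2d)
  if (nrow(v) < nx || ncol(v) < ny) {
    stop("source map smaller than the requested sampling grid")
  }
  ri <- round(seq(1, nrow(v), length.out = nx))
  ci <- round(seq(1, ncol(v), length.out = ny))
  pitch <- if (inherits(map2d, "spatial_map")) map2d$pitch else NA_real_
  spatial_map(v[ri, ci, drop = FALSE], pitch = pitch)
}

#' Normalize a map to a reference level
#'
#' Divides by the ROI mean (default: the map's own mean) so the full-ROI
#' normalized map has mean exactly 1, as in per-dose normalized
#' specific-energy maps.
#'
#' @param map2d Matrix or [spatial_map()].
#' @param reference Positive reference value; defaults to `mean(map2d)`.
#' @return A [spatial_map()] with unit mean when `reference` is the ROI mean.
#' @export
normalize_map <- function(map2d, reference = NULL) {
  v <- map_values(map2d)
  if (is.null(reference)) reference <- mean(v)
  if (!is.finite(reference) || reference <= 0) {
    stop("normalization reference must be > 0")
  }
  pitch <- if (inherits(map2d, "spatial_map")) map2d$pitch else NA_real_
  spatial_map(v / reference, pitch = pitch, reference = reference)
}

#' Central ROI slice of a field as a 2D map
#'
#' Extracts the mid-depth slice and its central `size` x `size` voxels,
#' the default region used for spatial homogeneity analyses.
#'
#' @param field A [specific_energy_field()].
#' @param size ROI edge length in voxels (default 100).
#' @param slice Z-index; defaults to the middle slice.
#' @return A [spatial_map()] with pitch equal to the voxel dx.
#' @export
field_roi_map <- function(field, size = 100, slice = NULL) {
  stopifnot(inherits(field, "specific_energy_field"))
  d <- dim(field$values)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  size <- min(size, d[1], d[2])
  r0 <- floor((d[1] - size) / 2)
  c0 <- floor((d[2] - size) / 2)
  spatial_map(field$values[r0 + seq_len(size), c0 + seq_len(size), slice],
              pitch = field$geom$dx)
}
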