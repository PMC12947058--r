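#' Read and write specific-energy fields in 3ddose ASCII
#'
#' The 3ddose dialect used by EGSnrc-family voxel scoring: line 1 holds
#' `nx ny nz`; then `nx+1`, `ny+1` and `nz+1` voxel boundary coordinates in
#' cm; then `nx*ny*nz` values (Gy) in x-fastest order; then as many relative
#' uncertainties. `read_3ddose(write_3ddose(f)) == f` to the precision
#' stored (17 significant digits).
#'
#' @param field A [specific_energy_field()].
#' @param path File path.
#' @param density Active-layer density (g/cm^3) used to rebuild the
#'   geometry on read (default 1.2).
#' @return `read_3ddose` returns a [specific_energy_field()] with geometry
#'   derived from the boundary spacing; `write_3ddose` returns `path`
#'   invisibly.
#' @export
write_3ddose <- function(field, path) {
  stopifnot(inherits(field, "specific_energy_field"))
  d <- dim(field$values)
  g <- field$geom
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  writeLines(paste(d, collapse = " "), con)
  # boundaries in cm; voxel sizes are stored in um
  writeLines(fmt(seq(0, by = g$dx * 1e-4, length.out = d[1] + 1)), con)
  writeLines(fmt(seq(0, by = g$dy * 1e-4, length.out = d[2] + 1)), con)
  writeLines(fmt(seq(0, by = g$dz * 1e-4, length.out = d[3] + 1)), con)
  writeLines(fmt(as.numeric(field$values)), con)  # x-fastest array order
  unc <- field$uncertainty
  if (is.null(unc)) unc <- numeric(prod(d))
  writeLines(fmt(as.numeric(unc)), con)
  invisible(path)
}

#' @rdname write_3ddose
#' @export
read_3ddose <- function(path, density = 1.2) {
  tok <- scan(path, what = numeric(), quiet = TRUE)
  if (length(tok) < 3) stop("3ddose parse error: missing dimension line")
  d <- as.integer(tok[1:3])
  if (any(d < 1)) stop("3ddose parse error: dimensions must be >= 1")
  nb <- sum(d + 1)
  nv <- prod(d)
  need <- 3 + nb + nv
  if (length(tok) < need) {
    stop(sprintf(
      "3ddose parse error: expected %d boundary + %d value tokens, found %d",
      nb, nv, length(tok) - 3
    ))
  }
  pos <- 3
  take <- function(k) {
    out <- tok[(pos + 1):(pos + k)]
    pos <<- pos + k
    out
  }
  xb <- take(d[1] + 1)
  yb <- take(d[2] + 1)
  zb <- take(d[3] + 1)
  vals <- take(nv)
  unc <- if (length(tok) >= pos + nv) take(nv) else numeric(nv)
  if (any(diff(xb) <= 0) || any(diff(yb) <= 0) || any(diff(zb) <= 0)) {
    stop("3ddose parse error: boundaries must be strictly increasing")
  }
  geom <- voxel_geometry(mean(diff(xb)) * 1e4, mean(diff(yb)) * 1e4,
                         mean(diff(zb)) * 1e4, density = density)
  specific_energy_field(array(vals, dim = d), geom,
                        nominal_dose = mean(vals), provenance = "file",
                        uncertainty = array(unc, dim = d))
}

#' Read and write dose-response tables as CSV
#'
#' RFC-4180 CSV with a mandatory header: columns `dose`, `response` and
#' optionally `uncertainty`.
#'
#' @param curve A [dose_response_curve()].
#' @param path File path.
#' @param modality Modality label applied on read.
#' @return `read_curve_csv` returns a [dose_response_curve()];
#'   `write_curve_csv` returns `path` invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "dose_response_curve"))
  df <- data.frame(dose = curve$doses, response = curve$responses)
  if (!is.null(curve$uncertainties)) df$uncertainty <- curve$uncertainties
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path, modality = c("OD", "RS")) {
  df <- utils::read.csv(path)
  if (!all(c("dose", "response") %in% names(df))) {
    stop("curve CSV must have 'dose' and 'response' columns")
  }
  dose_response_curve(df$dose, df$response,
                      uncertainties = df[["uncertainty"]],
                      modality = match.arg(modality))
}

#' Read and write 16-bit grayscale scans
#'
#' `read_scan` accepts 16-bit grayscale TIFF or PNG and returns integer
#' transmission readings in `[1, 65535]` (multi-channel images are reduced
#' to the requested channel). `write_scan` writes 16-bit TIFF.
#'
#' @param path File path (`.tif`, `.tiff` or `.png`).
#' @param channel Channel index for RGB input (1 = red, the analysis
#'   default).
#' @param dpi,dose Metadata attached to the returned [od_scan()].
#' @return `read_scan` returns an [od_scan()]; `write_scan` returns `path`
#'   invisibly.
#' @export
read_scan <- function(path, channel = 1, dpi = 300, dose = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported scan format: .", ext)
  )
  if (length(dim(img)) == 3) img <- img[, , channel]
  px <- round(img * 65535)
  px[px < 1] <- 1
  od_scan(px, dpi = dpi, dose = dose,
          channel = c("red", "green", "blue")[min(channel, 3)])
}

#' @rdname read_scan
#' @param scan An [od_scan()] (or matrix of readings in `[1, 65535]`).
#' @export
write_scan <- function(scan, path) {
  px <- scan_pixels(scan)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read and write stacked Raman spectra as CSV
#'
#' Column 1 is the Raman shift axis (`shift`, cm^-1, strictly increasing);
#' each further column is one spectrum.
#'
#' @param path File path.
#' @param shifts Axis (cm^-1).
#' @param intensities Matrix, channels x spectra.
#' @return `read_spectra_stack` returns a list with `shifts` and
#'   `intensities`; `write_spectra_stack` returns `path` invisibly.
#' @export
read_spectra_stack <- function(path) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "shift") {
    stop("spectra CSV must have a leading 'shift' column")
  }
  shifts <- df[[1]]
  if (is.unsorted(shifts, strictly = TRUE)) {
    stop("Raman shift axis must be strictly increasing")
  }
  list(shifts = shifts,
       intensities = as.matrix(df[, -1, drop = FALSE]))
}

#' @rdname read_spectra_stack
#' @export
write_spectra_stack <- function(shifts, intensities, path) {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == length(shifts))
  df <- data.frame(shift = shifts, intensities)
  names(df) <- c("shift", paste0("s", seq_len(ncol(intensities))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration files
#'
#' YAML (or JSON) configuration holding the dose list, geometry preset,
#' engine family and anchors, film parameters, seed and output directory.
#' Configurations round-trip losslessly, and `read_run_config` records the
#' file's MD5 hash so every run can log which configuration produced it.
#'
#' @param config Named list.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `read_run_config` returns the configuration list with an
#'   attribute `hash`; `write_run_config` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  config <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  attr(config, "hash") <- unname(tools::md5sum(path))
  config
}
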