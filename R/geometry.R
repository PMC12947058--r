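#' Rectangular scoring-voxel geometry
#'
#' Describes the micron-scale rectangular voxels in which specific energy is
#' scored inside the film's 28-um active layer. Two presets mirror the scoring
#' arrays used for the two readout modalities: `"vx-sm"`
#' (0.8862 x 0.8862 x 6 um, the Raman sampling volume) and `"vx-lg"`
#' (1.436 x 1.436 x 9.4 um, the average monomer-crystal size).
#'
#' @param dx,dy,dz Voxel edge lengths in micrometres. Must be positive.
#' @param density Mass density of the active layer in g/cm^3 (default 1.2).
#'
#' @return An object of class `voxel_geometry`: a list with elements `dx`,
#'   `dy`, `dz` (um), `density` (g/cm^3), `volume` (um^3), `mass` (kg) and
#'   `mean_chord` (um, the Cauchy 4V/S chord length).
#' @export
#' @examples
#' voxel_geometry(1, 1, 1)$mean_chord  # 2/3 for a unit cube
#' voxel_geometry_preset("vx-sm")
voxel_geometry <- function(dx, dy, dz, density = 1.2) {
  dims <- c(dx = dx, dy = dy, dz = dz)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("invalid geometry: all voxel dimensions must be positive and finite")
  }
  if (!is.finite(density) || density <= 0) {
    stop("invalid geometry: density must be positive")
  }
  volume <- dx * dy * dz                      # um^3
  surface <- 2 * (dx * dy + dy * dz + dx * dz)  # um^2
  structure(list(
    dx = dx, dy = dy, dz = dz,
    density = density,
    volume = volume,
    # g/cm^3 * um^3 -> kg: 1 um^3 = 1e-12 cm^3, 1 g = 1e-3 kg
    mass = density * volume * 1e-15,
    mean_chord = 4 * volume / surface
  ), class = "voxel_geometry")
}

#' @rdname voxel_geometry
#' @param preset Name of a preset geometry, `"vx-sm"` or `"vx-lg"`.
#' @export
voxel_geometry_preset <- function(preset = c("vx-sm", "vx-lg"),
                                  density = 1.2) {
  preset <- match.arg(preset)
  switch(preset,
    "vx-sm" = voxel_geometry(0.8862, 0.8862, 6, density = density),
    "vx-lg" = voxel_geometry(1.436, 1.436, 9.4, density = density)
  )
}

#' Mean chord length of a voxel
#'
#' Cauchy's formula for convex bodies: the mean length of random straight-line
#' traversals is 4V/S. At low dose the peak of the specific-energy
#' distribution corresponds to a single electron crossing this chord.
#'
#' @param geom A [voxel_geometry()].
#' @return Mean chord length in micrometres.
#' @export
mean_chord_length <- function(geom) {
  stopifnot(inherits(geom, "voxel_geometry"))
  geom$mean_chord
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf(
    "voxel geometry: %.4g x %.4g x %.4g um, density %.3g g/cm^3\n",
    x$dx, x$dy, x$dz, x$density
  ))
  cat(sprintf("  volume %.4g um^3, mass %.4g kg, mean chord %.4g um\n",
              x$volume, x$mass, x$mean_chord))
  invisible(x)
}
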