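# Bridging arithmetic between molecular geometry / areal densities and the
# dimensionless area fractions used by the simulation engines.

#' Molecular footprint of a membrane protein
#'
#' Describes the two-dimensional exclusion footprint of a molecule as either
#' a rectangle (length x width) or a disc (radius). The receptor default is
#' the 16 x 8 nm extracellular domain of an AMPA receptor (128 nm^2); a
#' PSD-95 scaffold protein is a disc of radius 2.5 nm.
#'
#' @param shape `"rectangle"` or `"disc"`.
#' @param length,width rectangle sides, nm.
#' @param radius disc radius, nm.
#' @return an object of class `molecular_footprint` with the computed
#'   `exclusion_area_nm2`.
#' @export
#' @examples
#' molecular_footprint("rectangle", length = 16, width = 8)
#' molecular_footprint("disc", radius = 2.5)
molecular_footprint <- function(shape = c("rectangle", "disc"),
                                length = NULL, width = NULL, radius = NULL) {
  shape <- match.arg(shape)
  if (shape == "rectangle") {
    if (is.null(length) || is.null(width) || length <= 0 || width <= 0)
      stopf("rectangle needs positive length and width")
    area <- length * width
  } else {
    if (is.null(radius) || radius <= 0) stopf("disc needs a positive radius")
    area <- pi * radius^2
  }
  structure(list(shape = shape, length = length, width = width,
                 radius = radius, exclusion_area_nm2 = area),
            class = "molecular_footprint")
}

#' @export
print.molecular_footprint <- function(x, ...) {
  dims <- if (x$shape == "rectangle")
    sprintf("%g x %g nm", x$length, x$width) else sprintf("radius %g nm", x$radius)
  cat(sprintf("%s footprint (%s): %.4g nm^2 = %.4g x 1e-6 um^2\n",
              x$shape, dims, x$exclusion_area_nm2, x$exclusion_area_nm2 * 1e-6 * 1e6))
  invisible(x)
}

#' Exclusion area of a molecular footprint
#'
#' @param footprint a [molecular_footprint()].
#' @return exclusion area in nm^2.
#' @export
#' @examples
#' exclusion_area(molecular_footprint("rectangle", length = 16, width = 8))
exclusion_area <- function(footprint) {
  stopifnot(inherits(footprint, "molecular_footprint"))
  footprint$exclusion_area_nm2
}

#' Membrane area fraction from molecular density
#'
#' The fraction of membrane area occupied by the total exclusion area of a
#' molecule population: density (per \eqn{\mu m^2}) times per-molecule
#' exclusion area. Supply either `density`, or `count` plus
#' `region_area_um2` (the count is converted to a density first).
#'
#' @param density molecules per \eqn{\mu m^2}.
#' @param exclusion_area_nm2 per-molecule exclusion area, nm^2.
#' @param count molecule count (alternative to `density`).
#' @param region_area_um2 region area, \eqn{\mu m^2} (with `count`).
#' @return dimensionless area fraction.
#' @export
#' @examples
#' area_fraction_from_density(5, 128)       # extrasynaptic receptors
#' area_fraction_from_density(3000, 19.64)  # scaffold proteins in the PSD
area_fraction_from_density <- function(density = NULL, exclusion_area_nm2,
                                       count = NULL, region_area_um2 = NULL) {
  if (is.null(density)) {
    if (is.null(count) || is.null(region_area_um2))
      stopf("supply density, or count with region_area_um2")
    density <- count / region_area_um2
  }
  if (density < 0 || exclusion_area_nm2 <= 0)
    stopf("density must be >= 0 and exclusion area positive")
  frac <- density * exclusion_area_nm2 * 1e-6   # nm^2 -> um^2
  if (frac > 1)
    stopf("over-packing error: area fraction %.3g exceeds 1", frac)
  frac
}

#' Areal density from a molecule count
#'
#' @param count number of molecules.
#' @param radius_nm radius of a disc-shaped region, nm (alternative to
#'   `area_um2`).
#' @param area_um2 region area, \eqn{\mu m^2}.
#' @return density in molecules per \eqn{\mu m^2}.
#' @export
#' @examples
#' density_from_count(20, radius_nm = 100)   # ~637 um^-2
#' density_from_count(100, radius_nm = 100)  # ~3183 um^-2
density_from_count <- function(count, radius_nm = NULL, area_um2 = NULL) {
  if (count < 0) stopf("count must be >= 0")
  if (is.null(area_um2)) {
    if (is.null(radius_nm) || radius_nm <= 0)
      stopf("supply area_um2 or a positive radius_nm")
    area_um2 <- pi * (radius_nm * 1e-3)^2
  }
  if (area_um2 <= 0) stopf("region area must be positive")
  count / area_um2
}
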