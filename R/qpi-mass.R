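#' Quantitative phase image container
#'
#' A 2D map of optical path-length shift in radians, co-registered with the
#' quadrant darkfield images, plus the wavelength and pixel geometry needed
#' to convert phase to dry-mass surface density.
#'
#' @param phase Numeric matrix, radians.
#' @param wavelength Wavelength in micrometres.
#' @param pixel_size Pixel pitch in micrometres.
#' @return Object of class `qdf_phase` with fields `phase`, `wavelength`,
#'   `pixel_size`, `pixel_area` (um^2).
#' @export
qdf_phase <- function(phase, wavelength, pixel_size) {
  stopifnot(is.matrix(phase), is.numeric(phase), all(is.finite(phase)),
            wavelength > 0, pixel_size > 0)
  structure(list(phase = phase, wavelength = wavelength,
                 pixel_size = pixel_size, pixel_area = pixel_size^2),
            class = "qdf_phase")
}

#' @export
print.qdf_phase <- function(x, ...) {
  cat(sprintf("Phase image %d x %d px, range [%.3f, %.3f] rad, lambda %.3f um\n",
              nrow(x$phase), ncol(x$phase), min(x$phase), max(x$phase),
              x$wavelength))
  invisible(x)
}

#' Remove the smooth phase background
#'
#' Masks the cells, fits a polynomial of total degree `degree` to the
#' remaining background pixels and subtracts the fitted surface from the raw
#' phase image, so that cell-free regions average to zero phase.
#'
#' @param p A [qdf_phase()].
#' @param cell_mask Logical matrix, TRUE over cells (and their halos); its
#'   complement is the background used for fitting. At least 30% of the
#'   field must remain background.
#' @param degree Polynomial total degree (default 8).
#' @return A corrected [qdf_phase()]; attribute `background_surface` holds
#'   the subtracted surface.
#' @export
correct_phase_background <- function(p, cell_mask, degree = 8) {
  stopifnot(inherits(p, "qdf_phase"), is.logical(cell_mask),
            identical(dim(cell_mask), dim(p$phase)))
  if (mean(!cell_mask) < 0.3)
    stop("cell mask covers too much of the field: need >= 30% background pixels")
  fit <- fit_background_poly(p$phase, !cell_mask, degree)
  out <- qdf_phase(fit$corrected, p$wavelength, p$pixel_size)
  attr(out, "background_surface") <- fit$surface
  out
}

#' Convert phase to dry-mass surface density
#'
#' Phase shift is proportional to the dry-mass surface density through the
#' specific refractive increment alpha:
#' `rho = phase * wavelength / (2 * pi * alpha)`, returned in pg/um^2
#' (with wavelength in um and alpha in m^3/kg the conversion factor is 1e-3).
#' The default alpha of 1.8e-4 m^3/kg is the standard cell-average value for
#' biomolecular dry mass.
#'
#' @param p A background-corrected [qdf_phase()].
#' @param alpha Specific refractive increment in m^3/kg.
#' @return Numeric matrix of density in pg/um^2; exactly linear in phase.
#' @examples
#' p <- qdf_phase(matrix(1, 4, 4), wavelength = 0.5, pixel_size = 1)
#' density_map(p)[1, 1]  # 0.442 pg/um^2
#' @export
density_map <- function(p, alpha = 1.8e-4) {
  stopifnot(inherits(p, "qdf_phase"), alpha > 0)
  p$phase * p$wavelength * 1e-3 / (2 * pi * alpha)
}

#' Per-cell dry mass from a density map and a label image
#'
#' Sums the dry-mass surface density over each labelled cell and multiplies
#' by the pixel area. Negative corrected-phase pixels inside cells are kept
#' (clipping them would bias mass upward).
#'
#' @param density Density matrix in pg/um^2 (see [density_map()]).
#' @param labels Integer label matrix; 0 is background.
#' @param pixel_area Pixel area in um^2.
#' @return Data frame with columns `label`, `area_px`, `mass_pg`.
#' @export
cell_dry_mass <- function(density, labels, pixel_area) {
  stopifnot(is.matrix(density), identical(dim(density), dim(labels)),
            pixel_area > 0, all(labels >= 0))
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    warning("no labelled cells; returning empty mass table")
    return(data.frame(label = integer(0), area_px = integer(0),
                      mass_pg = numeric(0)))
  }
  sel <- labels > 0
  f <- factor(labels[sel], levels = ids)
  sums <- as.numeric(rowsum(density[sel], f))
  data.frame(label = as.integer(ids),
             area_px = as.integer(table(f)),
             mass_pg = sums * pixel_area)
}

#' Mass per unit footprint area
#'
#' Dry mass divided by footprint area, pg/um^2 -- a shape proxy: rounded
#' cells pack the same mass into a smaller footprint.
#'
#' @param mass Mass in pg.
#' @param area Footprint area in um^2 (must be positive).
#' @return mass / area.
#' @export
mass_per_area <- function(mass, area) {
  stopifnot(is.numeric(mass), is.numeric(area))
  if (any(area <= 0)) stop("area must be positive")
  mass / area
}
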