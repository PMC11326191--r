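#' Optical system description for quadrant darkfield imaging
#'
#' Bundles the acquisition parameters of an LED-array darkfield microscope in
#' which the darkfield illumination annulus is split into four quadrants
#' (top-left, top-right, bottom-left, bottom-right), one image being acquired
#' under each. The annulus must lie outside the objective NA (the darkfield
#' condition), so only light scattered or refracted into the objective forms
#' the image.
#'
#' @param wavelength Illumination wavelength in micrometres.
#' @param objective_na Objective numerical aperture (dimensionless).
#' @param annulus_na_range Inner and outer NA of the illumination annulus.
#'   Both must exceed `objective_na`.
#' @param pixel_size Sample-plane pixel pitch in micrometres.
#' @param psf_sigma Standard deviation of the Gaussian point-spread function
#'   in micrometres. Defaults to the diffraction-limited estimate
#'   `0.21 * wavelength / objective_na`.
#' @param bit_depth Camera container bit depth; one of 8, 12, 16.
#' @param quadrant_azimuths Named numeric vector of the four illumination
#'   azimuths in degrees: the direction from the field centre *toward* the
#'   illuminating LED quadrant, in image coordinates with y increasing
#'   downward and angles measured from the +x axis (so top-left is 225).
#'   Names must be `TL`, `TR`, `BL`, `BR`. With this convention the
#'   boundary arc *opposite* the illumination lights up: a top-left
#'   illuminated bead shows its bottom-right rim.
#'
#' @return An object of class `qdf_optics`.
#' @examples
#' opt <- qdf_optics()
#' opt$psf_sigma
#' @export
qdf_optics <- function(wavelength = 0.532,
                       objective_na = 0.25,
                       annulus_na_range = c(1.05, 1.33) * objective_na,
                       pixel_size = 0.586,
                       psf_sigma = 0.21 * wavelength / objective_na,
                       bit_depth = 16,
                       quadrant_azimuths = c(TL = 225, TR = 315, BL = 135, BR = 45)) {
  stopifnot(is.numeric(wavelength), wavelength > 0,
            is.numeric(objective_na), objective_na > 0,
            length(annulus_na_range) == 2,
            is.numeric(pixel_size), pixel_size > 0,
            is.numeric(psf_sigma), psf_sigma > 0)
  if (min(annulus_na_range) <= objective_na)
    stop("darkfield condition violated: annulus inner NA must exceed the objective NA")
  if (!bit_depth %in% c(8, 12, 16))
    stop("bit_depth must be one of 8, 12, 16")
  if (!setequal(names(quadrant_azimuths), c("TL", "TR", "BL", "BR")))
    stop("quadrant_azimuths must be named TL, TR, BL, BR")
  structure(list(
    wavelength = wavelength,
    objective_na = objective_na,
    annulus_na_range = sort(annulus_na_range),
    pixel_size = pixel_size,
    psf_sigma = psf_sigma,
    bit_depth = bit_depth,
    quadrant_azimuths = quadrant_azimuths[c("TL", "TR", "BL", "BR")]
  ), class = "qdf_optics")
}

#' @export
print.qdf_optics <- function(x, ...) {
  cat("Quadrant darkfield optics\n")
  cat(sprintf("  wavelength   : %.3f um\n", x$wavelength))
  cat(sprintf("  objective NA : %.3f; annulus NA %.3f-%.3f\n",
              x$objective_na, x$annulus_na_range[1], x$annulus_na_range[2]))
  cat(sprintf("  pixel size   : %.3f um; PSF sigma %.3f um; %d-bit\n",
              x$pixel_size, x$psf_sigma, x$bit_depth))
  cat(sprintf("  azimuths     : TL=%g TR=%g BL=%g BR=%g deg\n",
              x$quadrant_azimuths["TL"], x$quadrant_azimuths["TR"],
              x$quadrant_azimuths["BL"], x$quadrant_azimuths["BR"]))
  invisible(x)
}

#' Co-registered set of four quadrant-illuminated darkfield images
#'
#' Container for the four intensity images captured under top-left, top-right,
#' bottom-left and bottom-right quadrant illumination, plus acquisition
#' metadata. All downstream reconstruction (darkfield summation, edge image,
#' QDF) operates pixel-wise on these four co-registered frames.
#'
#' @param tl,tr,bl,br Numeric matrices of identical dimensions (counts).
#' @param meta Named list of acquisition metadata (e.g. `exposure_ms`,
#'   `gain_db`, `bit_depth`, `wavelength`, `pixel_size`).
#' @return An object of class `qdf_quadrants`.
#' @export
qdf_quadrants <- function(tl, tr, bl, br, meta = list()) {
  imgs <- list(tl = tl, tr = tr, bl = bl, br = br)
  for (nm in names(imgs))
    if (!is.matrix(imgs[[nm]]) || !is.numeric(imgs[[nm]]))
      stop("quadrant '", nm, "' must be a numeric matrix")
  d <- dim(tl)
  if (!all(vapply(imgs, function(m) identical(dim(m), d), logical(1))))
    stop("all four quadrant images must have identical dimensions")
  structure(c(imgs, list(meta = meta)), class = "qdf_quadrants")
}

#' @export
print.qdf_quadrants <- function(x, ...) {
  d <- dim(x$tl)
  cat(sprintf("Quadrant darkfield set: 4 x [%d x %d] images\n", d[1], d[2]))
  rng <- range(c(x$tl, x$tr, x$bl, x$br))
  cat(sprintf("  intensity range: [%g, %g] counts\n", rng[1], rng[2]))
  if (length(x$meta)) {
    m <- x$meta
    cat("  meta:", paste(names(m), unlist(lapply(m, format)), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}
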