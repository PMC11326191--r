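#' Render the four quadrant-illuminated darkfield images of a scene
#'
#' The optical forward model behind every synthetic test in the package. Two
#' scattering regimes are rendered:
#'
#' * *Edges (Snell regime).* Under illumination from azimuth direction `u`, a
#'   pixel of a body's height map with gradient `grad h` emits
#'   `edge_gain * max(0, grad h . u)` -- equivalently
#'   `edge_gain * |grad h| * max(0, -n . u)` with `n` the outward normal, so
#'   the boundary arc facing *away from* the illumination lights up and the
#'   lit arc rotates with the quadrant.
#' * *Puncta (Mie regime).* Each punctum scatters broadly and therefore
#'   deposits `amplitude / 4` identically into every quadrant.
#'
#' Both contributions are convolved with a Gaussian PSF, then stray light and
#' the smooth background polynomial are added, then Poisson shot noise,
#' Gaussian read noise and bit-depth quantization are applied. Frame seeds are
#' split deterministically from the scene seed (TL, TR, BL, BR use offsets
#' 1..4), so rendering is bit-reproducible.
#'
#' @param scene A [qdf_scene()].
#' @param optics A [qdf_optics()].
#' @return A [qdf_quadrants()] set; `meta$n_clipped` counts pixels whose
#'   noise-free composite would have been negative (clamped to zero).
#' @examples
#' sc <- qdf_scene(c(64, 64), puncta = punctum(16, 16, amplitude = 400),
#'                 shot_noise = FALSE, read_noise_sigma = 0)
#' q <- render_quadrants(sc, qdf_optics(pixel_size = 0.5))
#' sum(q$tl)  # 100: one quarter of the punctum amplitude
#' @export
render_quadrants <- function(scene, optics) {
  stopifnot(inherits(scene, "qdf_scene"), inherits(optics, "qdf_optics"))
  ny <- scene$field_size[1]; nx <- scene$field_size[2]
  ps <- optics$pixel_size
  .check_scene_fits(scene, optics)

  az <- optics$quadrant_azimuths * pi / 180
  u <- cbind(cos(az), sin(az))  # y increases downward; azimuth from +x axis
  rownames(u) <- names(az)

  edge_src <- list(TL = matrix(0, ny, nx), TR = matrix(0, ny, nx),
                   BL = matrix(0, ny, nx), BR = matrix(0, ny, nx))
  for (b in scene$bodies) {
    h <- body_height_map(b, ny, nx, ps)
    g <- grad_xy(h, ps)
    for (q in names(edge_src)) {
      proj <- g$gx * u[q, 1] + g$gy * u[q, 2]
      proj[proj < 0] <- 0
      edge_src[[q]] <- edge_src[[q]] + b$edge_gain * proj
    }
  }
  pts <- splat_points(ny, nx, scene$puncta$x_um, scene$puncta$y_um,
                      scene$puncta$amplitude / 4, ps)

  base <- .scene_base(scene)
  sigma_px <- optics$psf_sigma / ps
  qmax <- 2^optics$bit_depth - 1
  n_clipped <- 0L
  out <- vector("list", 4); names(out) <- c("TL", "TR", "BL", "BR")
  for (k in seq_along(out)) {
    q <- names(out)[k]
    img <- gauss_blur(edge_src[[q]] + pts, sigma_px) + base
    neg <- img < 0
    if (any(neg)) { n_clipped <- n_clipped + sum(neg); img[neg] <- 0 }
    out[[k]] <- .apply_noise(img, scene, optics, seed_offset = k, qmax = qmax)
  }
  qdf_quadrants(tl = out$TL, tr = out$TR, bl = out$BL, br = out$BR,
                meta = list(bit_depth = optics$bit_depth,
                            wavelength = optics$wavelength,
                            pixel_size = ps, n_clipped = n_clipped))
}

.check_scene_fits <- function(scene, optics) {
  ny <- scene$field_size[1]; nx <- scene$field_size[2]
  ps <- optics$pixel_size
  xmax <- (nx - 1) * ps; ymax <- (ny - 1) * ps
  for (b in scene$bodies) {
    R <- body_footprint_radius(b)
    if (b$x_um - R < 0 || b$y_um - R < 0 ||
        b$x_um + R > xmax || b$y_um + R > ymax)
      stop("field too small: a body extends outside the field of view")
  }
  p <- scene$puncta
  if (nrow(p) && any(p$x_um < 0 | p$x_um > xmax | p$y_um < 0 | p$y_um > ymax))
    stop("puncta must lie inside the field")
  invisible(TRUE)
}

.scene_base <- function(scene) {
  ny <- scene$field_size[1]; nx <- scene$field_size[2]
  base <- eval_poly2d(scene$background_poly_coeffs, ny, nx)
  if (!is.null(scene$stray_light_frame)) base <- base + scene$stray_light_frame
  base
}

.apply_noise <- function(img, scene, optics, seed_offset, qmax) {
  noisy <- if (scene$shot_noise || scene$read_noise_sigma > 0) {
    with_seed(scene$seed + seed_offset, {
      x <- img
      if (scene$shot_noise) x <- matrix(stats::rpois(length(x), pmax(x, 0)),
                                        nrow(x), ncol(x))
      if (scene$read_noise_sigma > 0)
        x <- x + matrix(stats::rnorm(length(x), 0, scene$read_noise_sigma),
                        nrow(x), ncol(x))
      x
    })
  } else img
  q <- round(noisy)
  q[q < 0] <- 0
  q[q > qmax] <- qmax
  q
}

#' Render the quantitative-phase image of a scene
#'
#' Supplies the co-registered QPI channel the quantification pipeline
#' consumes (phase reconstruction from raw acquisitions is outside this
#' package's scope). Body phase is `(2 pi / wavelength) * delta_n * height`;
#' each punctum adds a small Gaussian bump of peak `punctum_phase_peak` and
#' sigma equal to its radius; the phase background polynomial (radians) and
#' Gaussian phase noise are added on top.
#'
#' @param scene A [qdf_scene()].
#' @param optics A [qdf_optics()].
#' @return A [qdf_phase()] object. Attribute `ground_truth` holds the
#'   noise-free per-body dry masses (pg, discrete pixel sums) and the
#'   body-only phase map.
#' @export
render_phase <- function(scene, optics) {
  stopifnot(inherits(scene, "qdf_scene"), inherits(optics, "qdf_optics"))
  ny <- scene$field_size[1]; nx <- scene$field_size[2]
  ps <- optics$pixel_size
  .check_scene_fits(scene, optics)
  phase <- matrix(0, ny, nx)
  body_mass <- numeric(length(scene$bodies))
  for (bi in seq_along(scene$bodies)) {
    b <- scene$bodies[[bi]]
    h <- body_height_map(b, ny, nx, ps)
    phi_b <- (2 * pi / optics$wavelength) * b$delta_n * h
    phase <- phase + phi_b
    # dry mass of this body on this grid (pg): rho = phi * lambda / (2 pi alpha)
    rho <- phi_b * optics$wavelength * 1e-3 / (2 * pi * 1.8e-4)
    body_mass[bi] <- sum(rho) * ps^2
  }
  clean <- phase
  if (nrow(scene$puncta) && scene$punctum_phase_peak > 0) {
    for (i in seq_len(nrow(scene$puncta))) {
      p <- scene$puncta[i, ]
      bump <- splat_points(ny, nx, p$x_um, p$y_um, 1, ps)
      bump <- gauss_blur(bump, max(p$radius_um / ps, 0.5))
      phase <- phase + scene$punctum_phase_peak * bump / max(bump)
    }
  }
  phase <- phase + eval_poly2d(scene$phase_background_coeffs, ny, nx)
  if (scene$phase_noise_sigma > 0)
    phase <- phase + with_seed(scene$seed + 5L,
      matrix(stats::rnorm(ny * nx, 0, scene$phase_noise_sigma), ny, nx))
  out <- qdf_phase(phase, wavelength = optics$wavelength, pixel_size = ps)
  attr(out, "ground_truth") <- list(body_mass_pg = body_mass,
                                    body_phase = clean)
  out
}

#' Render an empty-field reference darkfield frame
#'
#' The image of an empty reference position: stray light plus the smooth
#' background polynomial, with independent noise (seed offset 6). Subtracting
#' it from sample frames removes the additive background shared by all
#' positions.
#'
#' @param scene A [qdf_scene()] (bodies and puncta are ignored).
#' @param optics A [qdf_optics()].
#' @param seed_offset Integer noise-stream offset; change it to emulate a
#'   second independently acquired reference.
#' @return A numeric matrix of quantized counts.
#' @export
render_reference <- function(scene, optics, seed_offset = 6L) {
  stopifnot(inherits(scene, "qdf_scene"), inherits(optics, "qdf_optics"))
  base <- .scene_base(scene)
  base[base < 0] <- 0
  .apply_noise(base, scene, optics, seed_offset = seed_offset,
               qmax = 2^optics$bit_depth - 1)
}
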