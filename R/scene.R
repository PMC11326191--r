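#' Sub-cellular punctum specification
#'
#' A punctum models a sub-wavelength scatterer (an organelle such as a
#' melanosome or lysosome) in the Mie regime: its scattering cone is broad, so
#' to first order it contributes the same intensity under every illumination
#' quadrant. By construction it deposits `amplitude / 4` into each of the four
#' quadrant images before noise.
#'
#' @param x_um,y_um Position in micrometres (x along columns, y along rows,
#'   origin at the first pixel centre).
#' @param radius_um Physical radius in micrometres (used for the phase bump;
#'   the darkfield footprint is set by the PSF).
#' @param amplitude Total scattered intensity in camera counts, summed over
#'   the four quadrants.
#' @return A one-row data frame; rows from several calls can be combined with
#'   `rbind()`.
#' @export
punctum <- function(x_um, y_um, radius_um = 0.25, amplitude = 400) {
  stopifnot(all(radius_um > 0), all(amplitude >= 0))
  n <- length(x_um)
  data.frame(x_um = x_um, y_um = y_um,
             radius_um = rep_len(radius_um, n),
             amplitude = rep_len(amplitude, n))
}

#' Large-body specification (cell or bead phantom)
#'
#' A body is a circular object much larger than the wavelength whose boundary
#' refracts light directionally (Snell regime): under illumination from
#' azimuth u, a boundary element with outward normal n emits
#' `edge_gain * |grad h| * max(0, -n . u)`, i.e. the arc *opposite* the
#' illumination quadrant lights up.
#'
#' The height profile is a one-parameter family interpolating a flat disc and
#' an equal-volume hemisphere: at roundness `s` the footprint radius is
#' `(1-s) * radius_um + s * R_hemi` with `R_hemi = (3V / 2 pi)^(1/3)`, and the
#' profile is `H * (1 - (r/R)^2)^(s/2)` with `H` fixed by volume conservation.
#' `s = 0` is the flat disc of height `height_um`; `s = 1` is exactly the
#' equal-volume hemisphere. This mimics the mitotic flat-to-round transition
#' of adherent cells at constant volume.
#'
#' @param x_um,y_um Centre position in micrometres.
#' @param radius_um Footprint radius of the flat (roundness 0) disc.
#' @param height_um Height of the flat disc in micrometres.
#' @param roundness Shape parameter in \[0, 1\].
#' @param delta_n Refractive-index contrast over the medium (dimensionless).
#' @param edge_gain Edge emission strength, counts per unit height gradient.
#' @return An object of class `qdf_body`.
#' @export
qdf_body <- function(x_um, y_um, radius_um, height_um, roundness = 0,
                     delta_n = 0.04, edge_gain = 50) {
  stopifnot(radius_um > 0, height_um > 0, roundness >= 0, roundness <= 1,
            delta_n > 0, edge_gain >= 0)
  structure(list(x_um = x_um, y_um = y_um, radius_um = radius_um,
                 height_um = height_um, roundness = roundness,
                 delta_n = delta_n, edge_gain = edge_gain),
            class = "qdf_body")
}

#' Body volume (analytic, micrometres cubed)
#'
#' Volume of the flat reference disc, which the roundness family conserves.
#' @param body A [qdf_body()].
#' @return Volume in um^3.
#' @export
body_volume <- function(body) pi * body$radius_um^2 * body$height_um

#' Body footprint radius at its current roundness
#' @param body A [qdf_body()].
#' @return Footprint radius in micrometres.
#' @export
body_footprint_radius <- function(body) {
  r_hemi <- (3 * body_volume(body) / (2 * pi))^(1 / 3)
  (1 - body$roundness) * body$radius_um + body$roundness * r_hemi
}

# Height map of a body on the pixel grid. The dome height is renormalised so
# that the *discrete* pixel-sum volume equals the analytic flat-disc volume;
# this makes volume (and hence dry mass) conservation under morphing exact on
# the grid, not just in the continuum limit.
body_height_map <- function(body, ny, nx, pixel_size) {
  R <- body_footprint_radius(body)
  p <- body$roundness / 2
  xs <- (seq_len(nx) - 1) * pixel_size - body$x_um
  ys <- (seq_len(ny) - 1) * pixel_size - body$y_um
  r2 <- outer(ys^2, xs^2, `+`) / R^2
  inside <- r2 < 1
  h <- matrix(0, ny, nx)
  h[inside] <- (1 - r2[inside])^p
  V <- body_volume(body)
  s <- sum(h) * pixel_size^2
  if (s <= 0) stop("body footprint contains no pixel centres; field too coarse")
  h * (V / s)
}

#' Synthetic scene specification for the optical forward model
#'
#' Ground-truth container describing a field of view: large bodies (cells or
#' beads), isotropically scattering puncta, a smooth additive background
#' polynomial, optional stray light, and the noise model. The same scene
#' renders to quadrant darkfield images ([render_quadrants()]), a phase image
#' ([render_phase()]) and an empty-reference frame ([render_reference()]).
#'
#' @param field_size Integer vector `c(ny, nx)` in pixels.
#' @param bodies List of [qdf_body()] objects.
#' @param puncta Data frame as produced by [punctum()] (possibly 0 rows).
#' @param background_poly_coeffs Coefficient matrix for [eval_poly2d()], in
#'   counts, added to every darkfield frame (total degree at most 8).
#' @param stray_light_frame Optional numeric matrix of stray-light counts.
#' @param read_noise_sigma Gaussian read-noise standard deviation in counts.
#' @param shot_noise Logical; apply Poisson shot noise to the pre-quantization
#'   signal.
#' @param phase_background_coeffs Coefficient matrix of the phase-channel
#'   background in radians.
#' @param phase_noise_sigma Phase read-out noise (radians).
#' @param punctum_phase_peak Peak phase bump a punctum adds to the phase
#'   image, radians.
#' @param seed Integer seed; frame seeds are split deterministically from it,
#'   so identical scenes render bit-identically.
#' @return An object of class `qdf_scene`.
#' @export
qdf_scene <- function(field_size,
                      bodies = list(),
                      puncta = punctum(numeric(0), numeric(0))[0, ],
                      background_poly_coeffs = matrix(0, 1, 1),
                      stray_light_frame = NULL,
                      read_noise_sigma = 2,
                      shot_noise = TRUE,
                      phase_background_coeffs = matrix(0, 1, 1),
                      phase_noise_sigma = 0.01,
                      punctum_phase_peak = 0.05,
                      seed = 1L) {
  stopifnot(length(field_size) == 2, all(field_size >= 4),
            is.list(bodies), is.data.frame(puncta),
            read_noise_sigma >= 0, phase_noise_sigma >= 0,
            punctum_phase_peak >= 0)
  field_size <- as.integer(field_size)
  if (nrow(background_poly_coeffs) - 1L > 8L)
    stop("background polynomial degree must be at most 8")
  if (!is.null(stray_light_frame) &&
      !identical(dim(stray_light_frame), as.integer(field_size)))
    stop("stray_light_frame must match field_size")
  for (b in bodies) stopifnot(inherits(b, "qdf_body"))
  scene <- structure(list(
    field_size = field_size, bodies = bodies, puncta = puncta,
    background_poly_coeffs = background_poly_coeffs,
    stray_light_frame = stray_light_frame,
    read_noise_sigma = read_noise_sigma, shot_noise = shot_noise,
    phase_background_coeffs = phase_background_coeffs,
    phase_noise_sigma = phase_noise_sigma,
    punctum_phase_peak = punctum_phase_peak,
    seed = as.integer(seed)), class = "qdf_scene")
  scene
}

#' @export
print.qdf_scene <- function(x, ...) {
  cat(sprintf("Synthetic QDF scene: %d x %d px, %d bodies, %d puncta, seed %d\n",
              x$field_size[1], x$field_size[2], length(x$bodies),
              nrow(x$puncta), x$seed))
  cat(sprintf("  noise: shot=%s, read sigma=%g counts; phase sigma=%g rad\n",
              x$shot_noise, x$read_noise_sigma, x$phase_noise_sigma))
  invisible(x)
}

# which body (index) contains each punctum; 0 if none
.punctum_body_index <- function(scene) {
  if (nrow(scene$puncta) == 0) return(integer(0))
  idx <- integer(nrow(scene$puncta))
  for (bi in seq_along(scene$bodies)) {
    b <- scene$bodies[[bi]]
    R <- body_footprint_radius(b)
    d <- sqrt((scene$puncta$x_um - b$x_um)^2 + (scene$puncta$y_um - b$y_um)^2)
    idx[idx == 0 & d < R] <- bi
  }
  idx
}

#' Morph a scene's bodies from flat towards rounded at constant volume
#'
#' Rescales every body's footprint and height profile to the requested
#' roundness while conserving body volume (hence dry mass) and the puncta
#' list: puncta positions contract affinely with the footprint of their
#' containing body, and their total scattered amplitude is untouched. This
#' emulates an adherent cell rounding up before division.
#'
#' @param scene A [qdf_scene()].
#' @param roundness Target roundness in \[0, 1\] applied to all bodies.
#' @return A new `qdf_scene`.
#' @export
morph_roundness <- function(scene, roundness) {
  stopifnot(inherits(scene, "qdf_scene"),
            roundness >= 0, roundness <= 1)
  owner <- .punctum_body_index(scene)
  out <- scene
  for (bi in seq_along(scene$bodies)) {
    b <- scene$bodies[[bi]]
    if (roundness == b$roundness) next
    R_old <- body_footprint_radius(b)
    b2 <- b
    b2$roundness <- roundness
    R_new <- body_footprint_radius(b2)
    out$bodies[[bi]] <- b2
    sel <- owner == bi
    if (any(sel)) {
      f <- R_new / R_old
      out$puncta$x_um[sel] <- b$x_um + (scene$puncta$x_um[sel] - b$x_um) * f
      out$puncta$y_um[sel] <- b$y_um + (scene$puncta$y_um[sel] - b$y_um) * f
      # guard: anything landing on/outside the new rim is pulled just inside
      d <- sqrt((out$puncta$x_um[sel] - b$x_um)^2 +
                (out$puncta$y_um[sel] - b$y_um)^2)
      bad <- d >= 0.98 * R_new
      if (any(bad)) {
        sc <- 0.95 * R_new / d
        i <- which(sel)[bad]
        out$puncta$x_um[i] <- b$x_um + (out$puncta$x_um[i] - b$x_um) * sc[bad]
        out$puncta$y_um[i] <- b$y_um + (out$puncta$y_um[i] - b$y_um) * sc[bad]
        message(sum(bad), " puncta repositioned to stay inside the shrunken body")
      }
    }
  }
  out
}

#' Sample a population of single-cell scenes
#'
#' Generates `n` one-cell scenes spanning a range of mass per area (a proxy of
#' cell rounding) with puncta content proportional to dry mass and independent
#' of shape -- the null model of a shape-independent organelle density. Mass
#' per area is drawn uniformly over `mass_per_area_range`; flatter cells
#' (lower mass per area) get proportionally larger footprints and lower
#' roundness. The per-cell puncta count is `round(puncta_per_mass * mass)` and
#' the per-punctum amplitude is rescaled so the *total* scattered amplitude is
#' exactly `amplitude_per_punctum * puncta_per_mass * mass`.
#'
#' @param template A [qdf_scene()] providing noise/background defaults and,
#'   when it contains a body, `delta_n` and `edge_gain`.
#' @param n Number of cells (at least 2).
#' @param mass_per_area_range Range of mass per area, pg/um^2.
#' @param puncta_per_mass Expected puncta per picogram of dry mass.
#' @param seed Integer seed (reproducible).
#' @param mass_range_pg Range of cell dry mass, pg.
#' @param amplitude_per_punctum Nominal per-punctum amplitude, counts.
#' @param alpha Specific refractive increment (m^3/kg) used to convert mass to
#'   body volume; see [density_map()].
#' @param wavelength Wavelength (um) used in the mass/volume conversion.
#' @param pixel_size Pixel pitch (um) used to size each field of view.
#' @return A list of `qdf_scene` objects; each carries an attribute
#'   `ground_truth`: list(mass_pg, area_um2, mass_per_area, n_puncta,
#'   total_amplitude).
#' @export
sample_population <- function(template, n, mass_per_area_range,
                              puncta_per_mass, seed,
                              mass_range_pg = c(150, 350),
                              amplitude_per_punctum = 400,
                              alpha = 1.8e-4,
                              wavelength = 0.532,
                              pixel_size = 0.586) {
  stopifnot(inherits(template, "qdf_scene"), n >= 2,
            length(mass_per_area_range) == 2,
            puncta_per_mass >= 0)
  if (diff(range(mass_per_area_range)) <= 0)
    stop("degenerate mass_per_area_range")
  proto <- if (length(template$bodies)) template$bodies[[1]] else
    qdf_body(1, 1, 1, 1)
  lo <- min(mass_per_area_range); hi <- max(mass_per_area_range)
  with_seed(seed, {
    mpa <- runif(n, lo, hi)
    mass <- runif(n, mass_range_pg[1], mass_range_pg[2])
    scenes <- vector("list", n)
    for (i in seq_len(n)) {
      area <- mass[i] / mpa[i]                      # um^2
      R0_fp <- sqrt(area / pi)                      # desired footprint radius
      s <- (mpa[i] - lo) / (hi - lo)                # rounder at high mpa
      # dry mass fixes body volume: mass[pg] = delta_n * V[um^3] * 1e-3/alpha
      V <- mass[i] * alpha * 1e3 / proto$delta_n    # um^3
      # invert footprint_radius(R0, h0, s) = R0_fp at volume V:
      # R_hemi depends only on V; R0 = (R_fp - s * R_hemi) / (1 - s) for s < 1
      r_hemi <- (3 * V / (2 * pi))^(1 / 3)
      R0 <- if (s < 0.999) (R0_fp - s * r_hemi) / (1 - s) else r_hemi
      R0 <- max(R0, r_hemi * 0.2)
      h0 <- V / (pi * R0^2)
      # empty border scales with the cell so background estimation (which
      # needs a healthy cell-free fraction of the field) stays well posed
      margin <- max(8, R0_fp)
      half <- R0_fp + margin
      npx <- 2 * ceiling(half / pixel_size) + 1
      cx <- (npx - 1) / 2 * pixel_size
      body <- qdf_body(cx, cx, R0, h0, roundness = s,
                       delta_n = proto$delta_n, edge_gain = proto$edge_gain)
      k <- max(0L, as.integer(round(puncta_per_mass * mass[i])))
      if (k > 0) {
        rad <- sqrt(runif(k)) * 0.8 * R0_fp
        th <- runif(k, 0, 2 * pi)
        amp <- amplitude_per_punctum * puncta_per_mass * mass[i] / k
        pts <- punctum(cx + rad * cos(th), cx + rad * sin(th),
                       amplitude = amp)
      } else pts <- punctum(numeric(0), numeric(0))[0, ]
      sc <- qdf_scene(field_size = c(npx, npx), bodies = list(body),
                      puncta = pts,
                      background_poly_coeffs = template$background_poly_coeffs,
                      read_noise_sigma = template$read_noise_sigma,
                      shot_noise = template$shot_noise,
                      phase_noise_sigma = template$phase_noise_sigma,
                      punctum_phase_peak = template$punctum_phase_peak,
                      seed = template$seed + i * 17L)
      attr(sc, "ground_truth") <- list(
        mass_pg = mass[i], area_um2 = area, mass_per_area = mpa[i],
        n_puncta = k, total_amplitude = if (k > 0) sum(pts$amplitude) else 0)
      scenes[[i]] <- sc
    }
    scenes
  })
}
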