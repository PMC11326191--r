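#' Scale a raw image down to the camera's native bit depth
#'
#' Acquisition software often stores 12-bit camera data left-shifted in
#' 16-bit containers; dividing by 16 and rounding to the nearest integer
#' recovers the native 12-bit counts.
#'
#' @param image Numeric matrix of counts.
#' @param divisor Integer divisor (16 maps 16-bit containers to 12-bit data).
#' @return Integer-valued numeric matrix, `round(image / divisor)`.
#' @export
scale_to_bit_depth <- function(image, divisor = 16) {
  stopifnot(is.numeric(image), divisor >= 1)
  round(image / divisor)
}

#' Subtract an empty-field reference frame
#'
#' Removes the additive background (stray light, illumination bleed) measured
#' at an empty reference position. Negative differences are floored at zero
#' by default (darkfield signal is physically nonnegative). Inside the
#' reconstruction chain the floor is disabled: rectifying the zero-mean
#' difference noise would add a positive bias to exactly the pixels that
#' carry no signal, which the later polynomial background fit would then
#' wrongly remove from signal pixels.
#'
#' @param image,reference Numeric matrices of identical shape.
#' @param floor_negative Floor negative differences at zero?
#' @return `image - reference`, floored at 0 when `floor_negative`.
#' @export
subtract_reference <- function(image, reference, floor_negative = TRUE) {
  if (!identical(dim(image), dim(reference)))
    stop("image and reference dimensions differ")
  out <- image - reference
  if (floor_negative) out[out < 0] <- 0
  out
}

#' Sum the four quadrant images into a conventional darkfield image
#'
#' @param q A [qdf_quadrants()] set.
#' @return Numeric matrix, `TL + TR + BL + BR` pixel-wise.
#' @export
sum_darkfield <- function(q) {
  stopifnot(inherits(q, "qdf_quadrants"))
  q$tl + q$tr + q$bl + q$br
}

#' Edge image: the anti-symmetric combination of opposing quadrants
#'
#' `E = |TL - BR| + |BL - TR|`, pixel-wise. Isotropic scatterers (puncta)
#' contribute equally to opposing quadrants and cancel exactly; directional
#' refraction at edges of large features survives, so E isolates edges.
#'
#' @param q A [qdf_quadrants()] set.
#' @return Nonnegative numeric matrix.
#' @export
edge_image <- function(q) {
  stopifnot(inherits(q, "qdf_quadrants"))
  abs(q$tl - q$br) + abs(q$bl - q$tr)
}

#' Quadrant darkfield image
#'
#' `QDF = c * DF - E`: the darkfield image scaled by the system calibration
#' factor minus the edge image, suppressing directional edge signal while
#' retaining isotropic puncta signal. Negative residuals are clipped to zero
#' by default (the signal is physically nonnegative); pass
#' `clip_negative = FALSE` for diagnostics and unbiased signal totals.
#'
#' @param df Darkfield image ([sum_darkfield()]).
#' @param e Edge image ([edge_image()]).
#' @param c_factor Scaling factor, typically 0.8-1.0; see [calibrate_c()].
#' @param clip_negative Clip negative pixels to zero?
#' @return Numeric matrix.
#' @export
qdf_image <- function(df, e, c_factor, clip_negative = TRUE) {
  if (!identical(dim(df), dim(e))) stop("df and e dimensions differ")
  stopifnot(is.numeric(c_factor), length(c_factor) == 1, c_factor > 0)
  out <- c_factor * df - e
  if (clip_negative) out[out < 0] <- 0
  out
}

#' Calibrate the QDF scaling factor from edge pixels
#'
#' The scaling factor c is system specific; it is chosen so that the scaled
#' darkfield matches the edge image at the edges of objects. Over the pixels
#' of `edge_mask` this is the least-squares solution of `c * DF ~ E`:
#' `c = sum(DF * E) / sum(DF^2)`.
#'
#' @param df Darkfield image.
#' @param e Edge image.
#' @param edge_mask Logical matrix selecting edge pixels; needs at least 100
#'   pixels with positive darkfield signal.
#' @return A `qdf_calibration` object: `c`, `edge_pixel_count`,
#'   `residual_rms` (counts).
#' @seealso [default_edge_mask()]
#' @export
calibrate_c <- function(df, e, edge_mask) {
  if (!identical(dim(df), dim(e)) || !identical(dim(df), dim(edge_mask)))
    stop("df, e and edge_mask dimensions differ")
  stopifnot(is.logical(edge_mask))
  sel <- edge_mask & is.finite(df) & is.finite(e)
  x <- df[sel]; y <- e[sel]
  if (sum(x > 0) < 100)
    stop("cannot calibrate: edge mask has fewer than 100 pixels with darkfield signal")
  cc <- sum(x * y) / sum(x * x)
  if (!is.finite(cc) || cc <= 0)
    stop("cannot calibrate: degenerate edge mask")
  structure(list(c = cc,
                 edge_pixel_count = sum(sel),
                 residual_rms = sqrt(mean((cc * x - y)^2))),
            class = "qdf_calibration")
}

#' @export
print.qdf_calibration <- function(x, ...) {
  cat(sprintf("QDF calibration: c = %.4f (%d edge pixels, residual RMS %.2f counts)\n",
              x$c, x$edge_pixel_count, x$residual_rms))
  invisible(x)
}

#' Default edge mask for calibration
#'
#' Pixels above a high quantile of the edge image, i.e. the brightest edge
#' arcs. Percentiles use linear interpolation between order statistics.
#'
#' @param e Edge image.
#' @param quantile_cut Quantile in (0, 1); defaults to the top 1%.
#' @param min_pixels On small fields the quantile cut is relaxed until the
#'   mask holds at least this many pixels (calibration needs a minimum
#'   sample).
#' @return Logical matrix.
#' @export
default_edge_mask <- function(e, quantile_cut = 0.99, min_pixels = 200) {
  mask <- e > stats::quantile(e, quantile_cut, names = FALSE, type = 7)
  if (sum(mask) < min_pixels) {
    srt <- sort(e[e > 0], decreasing = TRUE)
    if (length(srt) >= min_pixels) mask <- e >= srt[min_pixels]
  }
  mask
}

#' Fit and remove a smooth 2D polynomial background
#'
#' Fits a 2D polynomial of total degree at most `degree` (all terms
#' `x^i y^j`, `i + j <= degree`) to the pixels flagged as background, by
#' ordinary least squares on coordinates normalised to \[-1, 1\], and
#' subtracts the fitted surface from the whole image. Degree 8 (45 terms)
#' matches common microscopy background-flattening practice for both phase
#' and darkfield channels.
#'
#' @param image Numeric matrix.
#' @param background_mask Logical matrix; TRUE marks background pixels. Must
#'   cover at least 5 pixels per polynomial coefficient.
#' @param degree Maximum total degree (default 8).
#' @param max_fit_pixels Background pixels are subsampled (deterministically,
#'   evenly spaced) to at most this many rows in the least-squares system.
#' @return List with `surface` (fitted background), `corrected`
#'   (`image - surface`), `coefficients` (matrix for [eval_poly2d()]) and
#'   `degree` actually used (lowered automatically if the design is
#'   rank-deficient).
#' @export
fit_background_poly <- function(image, background_mask, degree = 8,
                                max_fit_pixels = 20000) {
  stopifnot(is.matrix(image), is.logical(background_mask),
            identical(dim(image), dim(background_mask)),
            degree >= 0)
  ny <- nrow(image); nx <- ncol(image)
  n_terms <- (degree + 1) * (degree + 2) / 2
  idx <- which(background_mask)
  if (length(idx) < 5 * n_terms)
    stop("background mask too small: need at least ", 5 * n_terms, " pixels")
  if (length(idx) > max_fit_pixels)
    idx <- idx[seq(1L, length(idx), length.out = max_fit_pixels)]
  rows <- ((idx - 1L) %% ny) + 1L
  cols <- ((idx - 1L) %/% ny) + 1L
  Yb <- poly2d_basis(ny, degree)
  Xb <- poly2d_basis(nx, degree)
  deg_use <- degree
  repeat {
    keep <- which(outer(0:degree, 0:degree, `+`) <= deg_use, arr.ind = TRUE)
    A <- Yb[rows, keep[, 1], drop = FALSE] * Xb[cols, keep[, 2], drop = FALSE]
    fit <- stats::lm.fit(A, image[idx])
    if (!anyNA(fit$coefficients) || deg_use == 0) break
    deg_use <- deg_use - 1  # rank-deficient design: shrink the degree
  }
  coefs <- matrix(0, degree + 1, degree + 1)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  coefs[cbind(keep[, 1], keep[, 2])] <- beta
  surface <- Yb %*% coefs %*% t(Xb)
  list(surface = surface, corrected = image - surface,
       coefficients = coefs, degree = deg_use)
}

#' Reconstruct DF, E and QDF from one quadrant set
#'
#' The standard preprocessing chain applied to a raw quadrant acquisition:
#' per-quadrant bit-depth scaling, empty-reference subtraction, darkfield
#' summation and edge-image computation, polynomial background removal of the
#' darkfield and edge images over a background mask, calibration of the
#' scaling factor (unless supplied), and the final QDF combination.
#'
#' @param q Raw [qdf_quadrants()] (e.g. 12-bit data in 16-bit containers).
#' @param reference Empty-field reference frame at container scale, or NULL.
#' @param background_mask Logical matrix of cell-free pixels used for the
#'   polynomial fit; NULL skips background removal.
#' @param c_factor Numeric scaling factor, or `"auto"` to calibrate from the
#'   top-percentile edge pixels of this frame.
#' @param bit_divisor Container-to-native divisor (see [scale_to_bit_depth()]).
#' @param degree Background polynomial degree.
#' @param reference_mode The reference is an empty-field frame acquired under
#'   a single quadrant-illumination pattern. `"per_quadrant"` (default)
#'   subtracts it from each quadrant before Eq-style combination;
#'   `"darkfield"` subtracts `4 * reference` from the summed darkfield only
#'   (leaving the edge image's background to the polynomial fit).
#' @return List: `df`, `e`, `qdf` (clipped), `qdf_raw` (unclipped),
#'   `calibration` (a `qdf_calibration` or the fixed value wrapped in one).
#' @export
reconstruct_qdf <- function(q, reference = NULL, background_mask = NULL,
                            c_factor = "auto", bit_divisor = 16, degree = 8,
                            reference_mode = c("per_quadrant", "darkfield")) {
  stopifnot(inherits(q, "qdf_quadrants"))
  reference_mode <- match.arg(reference_mode)
  imgs <- lapply(q[c("tl", "tr", "bl", "br")], scale_to_bit_depth,
                 divisor = bit_divisor)
  ref <- if (!is.null(reference)) scale_to_bit_depth(reference, bit_divisor)
  if (!is.null(ref) && reference_mode == "per_quadrant")
    imgs <- lapply(imgs, subtract_reference, reference = ref,
                   floor_negative = FALSE)
  qs <- qdf_quadrants(imgs$tl, imgs$tr, imgs$bl, imgs$br, meta = q$meta)
  df <- sum_darkfield(qs)
  if (!is.null(ref) && reference_mode == "darkfield")
    df <- subtract_reference(df, 4 * ref, floor_negative = FALSE)
  e <- edge_image(qs)
  if (!is.null(background_mask)) {
    df <- fit_background_poly(df, background_mask, degree)$corrected
    e <- fit_background_poly(e, background_mask, degree)$corrected
  }
  cal <- if (identical(c_factor, "auto")) {
    calibrate_c(df, e, default_edge_mask(e))
  } else {
    stopifnot(is.numeric(c_factor), c_factor > 0)
    structure(list(c = c_factor, edge_pixel_count = NA_integer_,
                   residual_rms = NA_real_), class = "qdf_calibration")
  }
  list(df = df, e = e,
       qdf = qdf_image(df, e, cal$c, clip_negative = TRUE),
       qdf_raw = qdf_image(df, e, cal$c, clip_negative = FALSE),
       calibration = cal)
}
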