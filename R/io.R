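# TIFF input/output.
#
# Integer count images (quadrants, reference, label maps) are stored as
# 16-bit TIFF. Float images (DF/E/QDF, phase) are stored as 32-bit float
# TIFF; because float TIFF storage is only well defined on [0, 1], float
# images are divided by a fixed scale on write and multiplied back on read:
# 2^16 for count-valued images, 2*pi for phase (radians). Negative pixels
# are clipped at write time (all stored channels are physically
# nonnegative).

QDF_COUNT_SCALE <- 65536
QDF_PHASE_SCALE <- 2 * pi

#' Write / read an integer count image as 16-bit TIFF
#'
#' @param img Numeric matrix with values in \[0, 65535\].
#' @param path Output path.
#' @return `read_count_tiff` returns an integer-valued numeric matrix.
#' @export
write_count_tiff <- function(img, path) {
  stopifnot(is.matrix(img), min(img) >= 0, max(img) <= 65535)
  tiff::writeTIFF(round(img) / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_count_tiff
#' @export
read_count_tiff <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (!is.matrix(img)) stop("expected a single-channel TIFF: ", path)
  img
}

#' Write / read a float image as scaled 32-bit TIFF
#'
#' @param img Numeric matrix.
#' @param path File path.
#' @param scale Fixed storage scale: stored value is `pmax(img, 0) / scale`.
#'   Use `QDF_PHASE_SCALE` for phase images.
#' @return `read_float_tiff` returns a numeric matrix on the original scale.
#' @export
write_float_tiff <- function(img, path, scale = QDF_COUNT_SCALE) {
  stopifnot(is.matrix(img))
  x <- pmax(img, 0) / scale
  if (max(x) > 1) stop("image exceeds the fixed float storage scale")
  tiff::writeTIFF(x, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_float_tiff
#' @export
read_float_tiff <- function(path, scale = QDF_COUNT_SCALE) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  tiff::readTIFF(path) * scale
}

#' Write a quadrant set to disk
#'
#' Either as one 4-page TIFF (page order TL, TR, BL, BR) or as four files
#' suffixed `_TL.tif`, `_TR.tif`, `_BL.tif`, `_BR.tif`.
#'
#' @param q A [qdf_quadrants()] set (integer counts).
#' @param path Output path; for `format = "suffix"` the base path without
#'   the quadrant suffix (e.g. `"pos1_t1"` writes `pos1_t1_TL.tif`, ...).
#' @param format `"multipage"` or `"suffix"`.
#' @return The path(s) written, invisibly.
#' @export
write_quadrants <- function(q, path, format = c("multipage", "suffix")) {
  stopifnot(inherits(q, "qdf_quadrants"))
  format <- match.arg(format)
  imgs <- lapply(q[c("tl", "tr", "bl", "br")], function(m) round(m) / 65535)
  if (format == "multipage") {
    tiff::writeTIFF(unname(imgs), path, bits.per.sample = 16)
    invisible(path)
  } else {
    paths <- paste0(path, "_", c("TL", "TR", "BL", "BR"), ".tif")
    for (i in 1:4) tiff::writeTIFF(imgs[[i]], paths[i], bits.per.sample = 16)
    invisible(paths)
  }
}

#' Read a quadrant set from disk
#'
#' Accepts the path of a 4-page TIFF, or a base path for which the four
#' suffixed files `<base>_TL.tif` ... exist.
#'
#' @param path TIFF path or suffix base path.
#' @param meta Metadata list stored in the returned object.
#' @return A [qdf_quadrants()] set.
#' @export
read_quadrants <- function(path, meta = list()) {
  if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(pages) != 4)
      stop("quadrant TIFF must have exactly 4 pages: ", path)
    qdf_quadrants(pages[[1]], pages[[2]], pages[[3]], pages[[4]], meta = meta)
  } else {
    paths <- paste0(path, "_", c("TL", "TR", "BL", "BR"), ".tif")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing quadrant frame(s): ", paste(missing, collapse = ", "))
    imgs <- lapply(paths, read_count_tiff)
    qdf_quadrants(imgs[[1]], imgs[[2]], imgs[[3]], imgs[[4]], meta = meta)
  }
}

#' Write the ground truth of a scene as a JSON sidecar
#'
#' @param scene A [qdf_scene()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "qdf_scene"))
  gt <- attr(scene, "ground_truth")
  obj <- list(
    schema = "qdfim-scene/1",
    field_size = scene$field_size,
    seed = scene$seed,
    bodies = lapply(scene$bodies, function(b) unclass(b)),
    puncta = scene$puncta,
    read_noise_sigma = scene$read_noise_sigma,
    shot_noise = scene$shot_noise,
    ground_truth = gt)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
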