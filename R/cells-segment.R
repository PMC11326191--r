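#' Segment single cells from a phase image
#'
#' Watershed segmentation of the background-corrected phase image. The
#' recipe: the phase is Gaussian-smoothed; foreground is thresholded by
#' Otsu's method; a watershed with seed-suppression depth `h_depth`
#' (regional maxima shallower than `h_depth` radians do not found their own
#' object) splits touching cells; components smaller than `min_area` are
#' discarded and labels are renumbered consecutively.
#'
#' Cells thin out towards their margins, so a single global threshold loses
#' the faint skirt (and with it dry mass). A hysteresis step recovers it:
#' labels found on the Otsu (strong) foreground are propagated outward over
#' the weak foreground `phase > skirt_frac * otsu_threshold`.
#'
#' @param p A background-corrected [qdf_phase()].
#' @param min_area Minimum cell footprint in um^2.
#' @param h_depth Seed suppression depth in radians: minimum phase drop
#'   between a cell's peak and its contact with a neighbour.
#' @param smooth_sigma Gaussian smoothing sigma in um.
#' @param skirt_frac Weak-threshold fraction of the Otsu threshold for the
#'   hysteresis expansion (0 < skirt_frac <= 1; 1 disables it).
#' @return Integer label matrix (0 = background); every strong-foreground
#'   pixel is labelled and labels never extend beyond the weak foreground.
#' @export
segment_cells <- function(p, min_area = 50, h_depth = 0.15,
                          smooth_sigma = 1, skirt_frac = 0.2) {
  stopifnot(inherits(p, "qdf_phase"), min_area >= 0, h_depth > 0,
            skirt_frac > 0, skirt_frac <= 1)
  sm <- gauss_blur(p$phase, smooth_sigma / p$pixel_size)
  rng <- range(sm)
  if (diff(rng) <= 0) {
    warning("flat phase image: no cells found")
    return(matrix(0L, nrow(sm), ncol(sm)))
  }
  norm <- (sm - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  fg <- norm > thr
  if (!any(fg)) {
    warning("empty foreground: no cells found")
    return(matrix(0L, nrow(sm), ncol(sm)))
  }
  topo <- sm - rng[1]
  topo[!fg] <- 0
  labels <- EBImage::imageData(EBImage::watershed(EBImage::Image(topo),
                                                  tolerance = h_depth))
  labels <- matrix(as.integer(labels), nrow(sm), ncol(sm))
  labels[!fg] <- 0L
  if (skirt_frac < 1) {
    weak <- norm > skirt_frac * thr
    if (any(weak & labels == 0L)) {
      grown <- EBImage::propagate(EBImage::Image(norm),
                                  EBImage::Image(labels), mask = weak)
      labels <- matrix(as.integer(EBImage::imageData(grown)),
                       nrow(sm), ncol(sm))
    }
  }
  # drop small components, relabel 1..K in raster order of first pixel
  min_px <- min_area / p$pixel_area
  ids <- sort(unique(labels[labels > 0]))
  keep <- ids[tabulate(match(labels, ids))[seq_along(ids)] >= min_px]
  remap <- integer(max(ids, 0L) + 1L)
  remap[keep + 1L] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0
  out[pos] <- remap[labels[pos] + 1L]
  out
}

#' Per-label centroids and areas
#'
#' @param labels Integer label matrix.
#' @param pixel_size Pixel pitch in um.
#' @return Data frame `label`, `x_um`, `y_um`, `area_um2`.
#' @export
label_centroids <- function(labels, pixel_size) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0)
    return(data.frame(label = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_um2 = numeric(0)))
  sel <- which(labels > 0)
  f <- factor(labels[sel], levels = ids)
  rows <- ((sel - 1L) %% nrow(labels))
  cols <- ((sel - 1L) %/% nrow(labels))
  n <- as.integer(table(f))
  data.frame(label = as.integer(ids),
             x_um = as.numeric(rowsum(cols, f)) / n * pixel_size,
             y_um = as.numeric(rowsum(rows, f)) / n * pixel_size,
             area_um2 = n * pixel_size^2)
}

#' Foreground mask dilated to protect cell halos
#'
#' Union of all labels dilated by a disc; its complement is the background
#' used for polynomial fits and noise estimation.
#'
#' @param labels Integer label matrix.
#' @param dilate_px Dilation radius in pixels (default 5).
#' @return Logical matrix, TRUE over dilated cells.
#' @export
dilated_cell_mask <- function(labels, dilate_px = 5) {
  fg <- labels > 0
  if (!any(fg) || dilate_px <= 0) return(fg)
  kern <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
  EBImage::imageData(EBImage::dilate(EBImage::Image(fg * 1), kern)) > 0.5
}
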