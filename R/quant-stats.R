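#' Threshold mask isolating puncta in a QDF image
#'
#' The detection threshold is `k` times the `q`-th percentile of the
#' background signal of the image at hand (recomputed per image, so it
#' adapts to residual background level). Percentiles use linear
#' interpolation between order statistics.
#'
#' @param qdf QDF image matrix.
#' @param background_pixels Logical matrix flagging cell-free pixels; at
#'   least 1000 required.
#' @param k Threshold multiplier (default 4).
#' @param q Background percentile (default 99).
#' @return Logical matrix, TRUE where `qdf` exceeds the threshold; the
#'   threshold is attached as attribute `threshold`.
#' @export
puncta_mask <- function(qdf, background_pixels, k = 4, q = 99) {
  stopifnot(is.matrix(qdf), is.logical(background_pixels),
            identical(dim(qdf), dim(background_pixels)), k > 0,
            q > 0, q < 100)
  bg <- qdf[background_pixels]
  if (length(bg) < 1000)
    stop("need at least 1000 background pixels to set the puncta threshold")
  thr <- k * stats::quantile(bg, q / 100, names = FALSE, type = 7)
  structure(qdf > thr, threshold = thr)
}

#' Per-cell puncta signal-to-noise ratio
#'
#' The QDF signal of a cell is the mean over the intersection of its label
#' with the puncta threshold mask; the noise level is the standard deviation
#' of the background signal outside the (dilated) cells. SNR is reported per
#' cell and summarised as mean +/- standard deviation over cells.
#'
#' @param qdf QDF image matrix.
#' @param labels Integer label matrix.
#' @param mask Puncta mask from [puncta_mask()].
#' @param background_pixels Logical matrix of cell-free pixels.
#' @return List: `per_cell` (data frame `label`, `n_px`, `snr`; `snr` is NA
#'   for cells with no masked pixels), `mean`, `sd`, `noise_sd`.
#' @export
cell_snr <- function(qdf, labels, mask, background_pixels) {
  stopifnot(identical(dim(qdf), dim(labels)),
            identical(dim(qdf), dim(mask)),
            identical(dim(qdf), dim(background_pixels)))
  noise_sd <- stats::sd(qdf[background_pixels])
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("degenerate image: background standard deviation is zero")
  ids <- sort(unique(labels[labels > 0]))
  per <- data.frame(label = as.integer(ids), n_px = 0L, snr = NA_real_)
  for (i in seq_along(ids)) {
    sel <- labels == ids[i] & mask
    per$n_px[i] <- sum(sel)
    if (per$n_px[i] > 0) per$snr[i] <- mean(qdf[sel]) / noise_sd
  }
  ok <- per$snr[!is.na(per$snr)]
  list(per_cell = per,
       mean = if (length(ok)) mean(ok) else NA_real_,
       sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
       noise_sd = noise_sd)
}

#' Per-cell integrated darkfield and QDF signal
#'
#' Pixel sums of the darkfield and QDF images over each labelled cell
#' (background excluded). Totals are additive over disjoint labels.
#'
#' @param qdf,df Co-registered image matrices.
#' @param labels Integer label matrix.
#' @return Data frame `label`, `area_px`, `total_df`, `total_qdf`.
#' @export
per_cell_totals <- function(qdf, df, labels) {
  stopifnot(identical(dim(qdf), dim(labels)), identical(dim(df), dim(labels)))
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0)
    return(data.frame(label = integer(0), area_px = integer(0),
                      total_df = numeric(0), total_qdf = numeric(0)))
  sel <- labels > 0
  f <- factor(labels[sel], levels = ids)
  data.frame(label = as.integer(ids),
             area_px = as.integer(table(f)),
             total_df = as.numeric(rowsum(df[sel], f)),
             total_qdf = as.numeric(rowsum(qdf[sel], f)))
}

#' Pearson correlation coefficient
#'
#' Thin validated wrapper around [stats::cor()] requiring at least 3 paired
#' finite observations and nonzero variance in both variables.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Least-squares linear regression with an F-test against the constant model
#'
#' Fits `y ~ x` by ordinary least squares and compares it with the
#' intercept-only (horizontal line) null model using the F statistic
#' `F = (RSS0 - RSS1) / (RSS1 / (n - 2))` on (1, n-2) degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param alpha Significance level for the reported decision (default 0.05).
#' @return A `qdf_regression` object: `slope`, `intercept`, `f_statistic`,
#'   `p_value`, `pearson_r`, `n`, `reject_null`, `alpha`.
#' @export
linreg_ftest <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), alpha > 0, alpha < 1)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("degenerate x: all values equal")
  fit <- stats::lm(y ~ x)
  rss1 <- sum(stats::residuals(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  fstat <- (rss0 - rss1) / (rss1 / (n - 2))
  p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 f_statistic = fstat, p_value = p,
                 pearson_r = pearson_cor(x, y), n = n,
                 reject_null = p < alpha, alpha = alpha),
            class = "qdf_regression")
}

#' @export
print.qdf_regression <- function(x, ...) {
  cat(sprintf("Linear fit: y = %.4g + %.4g x  (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  F(1, %d) = %.4g, p = %.3g (%s at alpha = %g); Pearson r = %.3f\n",
              x$n - 2, x$f_statistic, x$p_value,
              if (x$reject_null) "slope significant" else "no slope", x$alpha,
              x$pearson_r))
  invisible(x)
}

#' Binned means and standard deviations of a scatter
#'
#' Bins `x` into half-open intervals `[lo, lo + bin_width)` anchored at
#' `origin` (a point exactly on an edge goes to the upper bin) and reports
#' the mean and standard deviation of `y` within each nonempty bin.
#'
#' @param x,y Numeric vectors.
#' @param bin_width Positive bin width in units of `x`.
#' @param origin Bin anchor (default 0).
#' @return Data frame `bin_lo`, `bin_mid`, `n`, `mean`, `sd` (sd is NA for
#'   singleton bins); empty bins are omitted.
#' @export
binned_scatter <- function(x, y, bin_width, origin = 0) {
  stopifnot(length(x) == length(y), bin_width > 0)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  idx <- floor((x - origin) / bin_width)
  sp <- split(y, idx)
  lev <- as.numeric(names(sp))
  o <- order(lev)
  data.frame(bin_lo = origin + lev[o] * bin_width,
             bin_mid = origin + (lev[o] + 0.5) * bin_width,
             n = vapply(sp[o], length, integer(1)),
             mean = vapply(sp[o], mean, numeric(1)),
             sd = vapply(sp[o], function(v)
               if (length(v) > 1) stats::sd(v) else NA_real_, numeric(1)),
             row.names = NULL)
}
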