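# Internal helpers.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so simulator determinism never perturbs user randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Gaussian blur with kernel truncated at ~4 sigma; sigma in pixels.
# Wraps EBImage::filter2 (FFT, circular boundary); objects are expected to be
# kept away from the field border by the scene margins.
gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  half <- max(1L, ceiling(4 * sigma_px))
  size <- 2L * half + 1L
  if (size > min(dim(img))) size <- (min(dim(img)) %/% 2L) * 2L - 1L
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
  k <- k / sum(k)  # exactly flux-preserving
  as.matrix(EBImage::filter2(img, k))
}

# Deposit point masses at sub-pixel positions by bilinear splatting.
# Positions in um; pixel (r, c) centre is at ((c-1) * ps, (r-1) * ps).
splat_points <- function(ny, nx, x_um, y_um, value, pixel_size) {
  img <- matrix(0, ny, nx)
  if (length(x_um) == 0) return(img)
  cx <- x_um / pixel_size + 1
  cy <- y_um / pixel_size + 1
  if (any(cx < 1 | cx > nx | cy < 1 | cy > ny))
    stop("puncta must lie inside the field")
  c0 <- pmin(floor(cx), nx - 1); r0 <- pmin(floor(cy), ny - 1)
  fx <- cx - c0; fy <- cy - r0
  add <- function(r, c, w) {
    i <- (c - 1) * ny + r
    for (k in seq_along(i)) img[i[k]] <<- img[i[k]] + value[k] * w[k]
  }
  value <- rep_len(value, length(cx))
  add(r0,     c0,     (1 - fx) * (1 - fy))
  add(r0,     c0 + 1, fx * (1 - fy))
  add(r0 + 1, c0,     (1 - fx) * fy)
  add(r0 + 1, c0 + 1, fx * fy)
  img
}

# central-difference gradient of a height map, in um of height per um
grad_xy <- function(h, pixel_size) {
  ny <- nrow(h); nx <- ncol(h)
  gx <- matrix(0, ny, nx); gy <- matrix(0, ny, nx)
  gx[, 2:(nx - 1)] <- (h[, 3:nx] - h[, 1:(nx - 2)]) / (2 * pixel_size)
  gy[2:(ny - 1), ] <- (h[3:ny, ] - h[1:(ny - 2), ]) / (2 * pixel_size)
  list(gx = gx, gy = gy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
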