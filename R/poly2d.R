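# Shared 2D polynomial machinery. Surfaces are parameterised on coordinates
# normalised to [-1, 1] in each axis, which keeps the degree-8 Vandermonde
# well conditioned. Coefficients are stored as a (d+1) x (d+1) matrix C with
# C[i+1, j+1] multiplying y_norm^i * x_norm^j; entries with i + j > d are
# ignored (kept zero).

poly2d_basis <- function(n, degree) {
  # powers 0..degree of the normalised coordinate for n pixels -> n x (d+1)
  u <- if (n == 1) 0 else seq(-1, 1, length.out = n)
  outer(u, 0:degree, `^`)
}

#' Evaluate a 2D polynomial surface over a pixel grid
#'
#' @param coeffs Square coefficient matrix; `coeffs[i+1, j+1]` multiplies
#'   `y^i * x^j` on coordinates normalised to \[-1, 1\].
#' @param ny,nx Output dimensions in pixels.
#' @return A `ny` x `nx` numeric matrix.
#' @export
eval_poly2d <- function(coeffs, ny, nx) {
  stopifnot(is.matrix(coeffs), nrow(coeffs) == ncol(coeffs))
  d <- nrow(coeffs) - 1L
  Y <- poly2d_basis(ny, d)
  X <- poly2d_basis(nx, d)
  C <- coeffs
  if (d > 0) {
    tot <- outer(0:d, 0:d, `+`)
    C[tot > d] <- 0
  }
  Y %*% C %*% t(X)
}
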