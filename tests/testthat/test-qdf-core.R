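test_that("bit-depth scaling divides and rounds to nearest integer", {
  expect_equal(scale_to_bit_depth(matrix(16380, 1, 1)), matrix(1024, 1, 1))
  expect_equal(scale_to_bit_depth(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(scale_to_bit_depth(matrix(4095 * 4, 3, 3), 16),
               matrix(1024, 3, 3))
  img <- matrix(c(7, 8, 24, 25), 2, 2)
  expect_true(all(scale_to_bit_depth(img, 16) == round(img / 16)))
})

test_that("reference subtraction floors at zero and fixes the background mean", {
  img <- matrix(c(5, 3, 10), 1, 3)
  expect_equal(subtract_reference(img, img), matrix(0, 1, 3))
  ref <- matrix(c(6, 1, 4), 1, 3)
  expect_equal(subtract_reference(img, ref), matrix(c(0, 2, 6), 1, 3))
  expect_error(subtract_reference(img, matrix(0, 2, 2)), "dimensions differ")

  # simulated empty scene: residual after reference subtraction is near zero
  # on background (floor biases it slightly positive, well under the noise sd)
  opt <- test_optics()
  coefs <- matrix(0, 2, 2); coefs[1, 1] <- 60
  sc <- qdf_scene(c(96, 96), background_poly_coeffs = coefs,
                  shot_noise = FALSE, read_noise_sigma = 2, seed = 9L)
  q <- render_quadrants(sc, opt)
  r <- render_reference(sc, opt)
  resid <- subtract_reference(q$tl, r)
  # the zero floor rectifies the difference noise: its mean is about
  # sigma_diff / sqrt(2 pi) ~ 1.1 counts here, well below sigma_diff
  expect_lt(mean(resid), 2)
})

test_that("darkfield summation is the pixel-wise quadrant sum", {
  q <- qdf_quadrants(matrix(5, 2, 2), matrix(5, 2, 2),
                     matrix(5, 2, 2), matrix(5, 2, 2))
  expect_equal(sum_darkfield(q), matrix(20, 2, 2))
  q2 <- qdf_quadrants(matrix(0, 2, 2), matrix(5, 2, 2),
                      matrix(5, 2, 2), matrix(5, 2, 2))
  expect_equal(sum_darkfield(q) - sum_darkfield(q2), matrix(5, 2, 2))
})

test_that("edge image: pixel formula, nonnegativity, swap invariance", {
  q <- qdf_quadrants(tl = matrix(5, 1, 1), br = matrix(2, 1, 1),
                     bl = matrix(1, 1, 1), tr = matrix(1, 1, 1))
  expect_equal(edge_image(q), matrix(3, 1, 1))  # |5-2| + |1-1|
  same <- qdf_quadrants(matrix(4, 3, 3), matrix(4, 3, 3),
                        matrix(4, 3, 3), matrix(4, 3, 3))
  expect_true(all(edge_image(same) == 0))
  # invariance under simultaneously swapping TL<->BR and BL<->TR
  set.seed(1)
  m <- function() matrix(rpois(25, 10), 5, 5)
  a <- m(); b <- m(); cc <- m(); d <- m()
  e1 <- edge_image(qdf_quadrants(tl = a, tr = b, bl = cc, br = d))
  e2 <- edge_image(qdf_quadrants(tl = d, tr = cc, bl = b, br = a))
  expect_identical(e1, e2)
  expect_true(all(e1 >= 0))
})

test_that("qdf_image combines, clips, and is linear pre-clip", {
  df <- matrix(4, 2, 2); e <- matrix(3, 2, 2)
  expect_equal(qdf_image(df, e, 1), matrix(1, 2, 2))
  expect_equal(qdf_image(df, e * 2, 1), matrix(0, 2, 2))        # clipped
  expect_equal(qdf_image(df, e * 2, 1, clip_negative = FALSE),
               matrix(-2, 2, 2))
  # linearity: qdf(a DF, a E, c) = a qdf(DF, E, c) for a > 0 (pre-clip)
  set.seed(2)
  df <- matrix(runif(36, 0, 10), 6, 6); e <- matrix(runif(36, 0, 10), 6, 6)
  a <- 3.7
  expect_equal(qdf_image(a * df, a * e, 0.9, clip_negative = FALSE),
               a * qdf_image(df, e, 0.9, clip_negative = FALSE))
  # with E = 0 (puncta only), QDF at c = 1 equals DF exactly
  expect_equal(qdf_image(df, matrix(0, 6, 6), 1), df)
})

test_that("calibrate_c recovers exact proportionality and rejects bad masks", {
  set.seed(3)
  df <- matrix(runif(400, 1, 100), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  expect_equal(calibrate_c(df, df, mask)$c, 1.0)
  cal <- calibrate_c(df, 0.9 * df, mask)
  expect_equal(cal$c, 0.9)
  expect_equal(cal$residual_rms, 0)
  expect_error(calibrate_c(df, df, matrix(FALSE, 20, 20)), "cannot calibrate")
  small <- matrix(FALSE, 20, 20); small[1:50] <- TRUE
  expect_error(calibrate_c(df, df, small), "fewer than 100")
})

test_that("calibrated c on a noisy bead recovers the noise-free edge ratio", {
  opt <- test_optics()
  clean <- bead_scene()
  qc <- render_quadrants(clean, opt)
  df0 <- sum_darkfield(qc); e0 <- edge_image(qc)
  mask <- default_edge_mask(e0)
  c_true <- calibrate_c(df0, e0, mask)$c

  noisy <- bead_scene(noise = TRUE, seed = 21L)
  qn <- render_quadrants(noisy, opt)
  dfn <- sum_darkfield(qn); en <- edge_image(qn)
  c_noisy <- calibrate_c(dfn, en, default_edge_mask(en))$c
  expect_equal(c_noisy, c_true, tolerance = 0.05)
})

test_that("background polynomial fit is exact on representable surfaces", {
  # known degree-3 surface, full mask
  coefs <- matrix(0, 4, 4)
  coefs[1, 1] <- 7; coefs[2, 2] <- 3; coefs[4, 1] <- -2; coefs[1, 3] <- 1.5
  img <- eval_poly2d(coefs, 48, 40)
  fit <- fit_background_poly(img, matrix(TRUE, 48, 40), degree = 3)
  expect_lt(max(abs(fit$corrected)) / max(abs(img)), 1e-6)
  # constant image
  fit2 <- fit_background_poly(matrix(7, 40, 40), matrix(TRUE, 40, 40), 2)
  expect_equal(fit2$surface, matrix(7, 40, 40), tolerance = 1e-10)
  # idempotence: fitting the corrected image gives a near-zero surface
  fit3 <- fit_background_poly(fit$corrected, matrix(TRUE, 48, 40), 3)
  expect_lt(sqrt(mean(fit3$surface^2)), 1e-8 * max(abs(img)))
  # mask too small
  expect_error(fit_background_poly(img, matrix(FALSE, 48, 40), 3),
               "mask too small")
})

test_that("degree-8 fit recovers the simulator background under the mask", {
  opt <- test_optics()
  coefs <- matrix(0, 4, 4)
  coefs[1, 1] <- 60; coefs[2, 1] <- 10; coefs[1, 2] <- -8; coefs[2, 2] <- 5
  sc <- qdf_scene(c(96, 96), bodies = list(qdf_body(24, 24, 14, 2)),
                  background_poly_coeffs = coefs,
                  read_noise_sigma = 2, seed = 4L)
  q <- render_quadrants(sc, opt)
  truth <- eval_poly2d(coefs, 96, 96)
  # mask out the body plus margin
  xs <- (seq_len(96) - 1) * 0.5
  d <- sqrt(outer((xs - 24)^2, (xs - 24)^2, `+`))
  bg <- d > 18
  fit <- fit_background_poly(q$tl, bg, degree = 8)
  rms <- sqrt(mean((fit$surface[bg] - truth[bg])^2))
  expect_lt(rms, 2)  # below the read-noise sigma
})

test_that("reconstruct_qdf chains the stages and honours a fixed c", {
  opt <- test_optics()
  sc <- bead_scene(puncta = punctum(32, 32, amplitude = 2000))
  q <- render_quadrants(sc, opt)
  # container-scale copy (12-bit data stored x16 in 16-bit container)
  q16 <- qdf_quadrants(q$tl * 16, q$tr * 16, q$bl * 16, q$br * 16,
                       meta = q$meta)
  rec <- reconstruct_qdf(q16, c_factor = "auto")
  expect_equal(dim(rec$qdf), dim(q$tl))
  expect_gt(rec$calibration$c, 0.8)
  expect_lt(rec$calibration$c, 1.2)
  # edge pixels suppressed, punctum retained
  e <- rec$e
  edge_px <- e > 0.2 * max(e)
  expect_lt(sum(rec$qdf[edge_px]) / sum(rec$df[edge_px]), 0.05)
  ctr <- 32 / 0.5 + 1
  expect_gt(rec$qdf[ctr, ctr] / rec$df[ctr, ctr], 0.95)
  rec2 <- reconstruct_qdf(q16, c_factor = 0.9)
  expect_equal(rec2$calibration$c, 0.9)
  expect_equal(rec2$qdf_raw, 0.9 * rec2$df - rec2$e)
})
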