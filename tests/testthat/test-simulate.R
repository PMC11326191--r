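test_that("puncta scatter isotropically: equal quadrants, zero edge image", {
  opt <- test_optics()
  sc <- qdf_scene(c(64, 64),
                  puncta = punctum(c(16, 20.3), c(16, 11.7),
                                   amplitude = c(400, 250)),
                  shot_noise = FALSE, read_noise_sigma = 0)
  q <- render_quadrants(sc, opt)
  expect_identical(q$tl, q$tr)
  expect_identical(q$tl, q$bl)
  expect_identical(q$tl, q$br)
  expect_true(all(edge_image(q) == 0))
  # each quadrant carries one quarter of the total amplitude (quantization
  # rounds pixel-wise, so allow a few counts)
  expect_equal(sum(q$tl), (400 + 250) / 4, tolerance = 0.05)
})

test_that("edge arcs light up opposite the illumination and rotate with it", {
  opt <- test_optics()
  q <- render_quadrants(bead_scene(), opt)
  thr <- 1
  expect_gt(sum(q$tl > thr), 0)
  # opposing quadrants light disjoint arcs of a convex body
  expect_equal(sum(q$tl > thr & q$br > thr), 0)
  expect_equal(sum(q$bl > thr & q$tr > thr), 0)
  # the TL-illuminated arc sits in the bottom-right half of the bead:
  # lit pixel centroid is displaced from the bead centre away from TL
  ctr <- 32 / 0.5 + 1
  lit <- which(q$tl > thr, arr.ind = TRUE)
  expect_gt(mean(lit[, "row"]), ctr)
  expect_gt(mean(lit[, "col"]), ctr)
  lit_br <- which(q$br > thr, arr.ind = TRUE)
  expect_lt(mean(lit_br[, "row"]), ctr)
  expect_lt(mean(lit_br[, "col"]), ctr)
})

test_that("a punctum inside a bead is visible in all four quadrants", {
  opt <- test_optics()
  sc <- bead_scene(puncta = punctum(32, 32, amplitude = 400))
  q <- render_quadrants(sc, opt)
  ctr <- 32 / 0.5 + 1
  for (img in list(q$tl, q$tr, q$bl, q$br))
    expect_gt(img[ctr, ctr], 5)
  # interior punctum cancels in the edge image
  e <- edge_image(q)
  expect_equal(e[ctr, ctr], 0)
})

test_that("rendering is deterministic under a fixed seed and noise differs across seeds", {
  opt <- test_optics()
  sc <- bead_scene(noise = TRUE, seed = 42L)
  q1 <- render_quadrants(sc, opt)
  q2 <- render_quadrants(sc, opt)
  expect_identical(q1$tl, q2$tl)
  expect_identical(q1$br, q2$br)
  sc2 <- bead_scene(noise = TRUE, seed = 43L)
  expect_false(identical(render_quadrants(sc2, opt)$tl, q1$tl))
})

test_that("scenes rejecting bodies outside the field and puncta validation", {
  opt <- test_optics()
  sc <- qdf_scene(c(32, 32), bodies = list(qdf_body(8, 8, 20, 3)))
  expect_error(render_quadrants(sc, opt), "field too small")
  sc2 <- qdf_scene(c(32, 32), puncta = punctum(100, 2))
  expect_error(render_quadrants(sc2, opt), "inside the field")
})

test_that("morph_roundness conserves volume and puncta, shrinks the footprint", {
  pts <- punctum(c(30, 36, 25), c(30, 33, 38), amplitude = c(100, 150, 200))
  sc <- bead_scene(puncta = pts)
  expect_identical(morph_roundness(sc, 0), sc)  # identity at roundness 0

  scm <- morph_roundness(sc, 1)
  b <- scm$bodies[[1]]
  # equal-volume hemisphere radius (closed form (3V / 2 pi)^(1/3))
  expect_equal(body_footprint_radius(b), 12.164403991146798, tolerance = 1e-12)
  expect_equal(body_volume(b), body_volume(sc$bodies[[1]]))
  # discrete volume conservation on the rendered grid, well under 0.1%
  h0 <- qdfim:::body_height_map(sc$bodies[[1]], 128, 128, 0.5)
  h1 <- qdfim:::body_height_map(b, 128, 128, 0.5)
  expect_equal(sum(h1), sum(h0), tolerance = 1e-10)
  # puncta count and total amplitude conserved; positions contracted affinely
  expect_equal(nrow(scm$puncta), nrow(sc$puncta))
  expect_equal(sum(scm$puncta$amplitude), sum(sc$puncta$amplitude))
  f <- 12.164403991146798 / 20
  expect_equal(scm$puncta$x_um, 32 + (sc$puncta$x_um - 32) * f)
  # footprint strictly decreases along the roundness path
  r <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s)
    body_footprint_radius(morph_roundness(sc, s)$bodies[[1]]), numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("morph_roundness repositions puncta that would escape the body", {
  pts <- punctum(51.9, 32, amplitude = 100)  # 0.1 um inside the flat rim
  sc <- bead_scene(puncta = pts)
  expect_message(scm <- morph_roundness(sc, 1), "repositioned")
  d <- sqrt((scm$puncta$x_um - 32)^2 + (scm$puncta$y_um - 32)^2)
  expect_lt(d, body_footprint_radius(scm$bodies[[1]]))
  expect_equal(nrow(scm$puncta), 1L)
})

test_that("render_phase matches closed-form slab phase and brute-force mass", {
  opt <- test_optics()
  # a wide flat disc approximates a uniform slab in its interior:
  # phase = 2 pi * delta_n * h / lambda = 0.6283 rad for dn 0.05, h 1, lam 0.5
  body <- qdf_body(30, 30, radius_um = 25, height_um = 1, delta_n = 0.05)
  sc <- qdf_scene(c(121, 121), bodies = list(body),
                  phase_noise_sigma = 0, shot_noise = FALSE,
                  read_noise_sigma = 0)
  opt2 <- qdf_optics(wavelength = 0.5, pixel_size = 0.5)
  ph <- render_phase(sc, opt2)
  ctr <- 30 / 0.5 + 1
  # slight excess over the continuum value reflects the discrete-volume
  # height renormalisation of the pixelated disc
  expect_equal(ph$phase[ctr, ctr], 0.6283185307179586, tolerance = 5e-3)

  # two-body scene: recorded ground-truth mass equals the pixel-wise sum of
  # the density map over each body (brute force)
  b1 <- qdf_body(20, 20, 10, 2, delta_n = 0.04)
  b2 <- qdf_body(45, 45, 8, 3, delta_n = 0.04)
  sc2 <- qdf_scene(c(121, 121), bodies = list(b1, b2), phase_noise_sigma = 0)
  ph2 <- render_phase(sc2, opt2)
  gt <- attr(ph2, "ground_truth")
  for (i in 1:2) {
    h <- qdfim:::body_height_map(sc2$bodies[[i]], 121, 121, 0.5)
    phi <- 2 * pi * 0.04 * h / 0.5
    rho <- phi * 0.5 * 1e-3 / (2 * pi * 1.8e-4)
    expect_equal(gt$body_mass_pg[i], sum(rho) * 0.25, tolerance = 1e-12)
  }
})

test_that("empty scene renders to background polynomial only", {
  opt <- test_optics()
  coefs <- matrix(0, 3, 3); coefs[1, 1] <- 40; coefs[2, 2] <- 5
  sc <- qdf_scene(c(64, 64), background_poly_coeffs = coefs,
                  shot_noise = FALSE, read_noise_sigma = 0,
                  phase_noise_sigma = 0)
  q <- render_quadrants(sc, opt)
  expect_equal(q$tl, round(eval_poly2d(coefs, 64, 64)))
  ph <- render_phase(sc, opt)
  expect_true(all(ph$phase == 0))
})

test_that("reference frame equals the scene background and differs only by noise", {
  opt <- test_optics()
  coefs <- matrix(0, 2, 2); coefs[1, 1] <- 50
  sc0 <- qdf_scene(c(64, 64), background_poly_coeffs = coefs,
                   shot_noise = FALSE, read_noise_sigma = 0)
  expect_equal(render_reference(sc0, opt), matrix(50, 64, 64))
  sc1 <- qdf_scene(c(64, 64), background_poly_coeffs = coefs,
                   read_noise_sigma = 2, seed = 7L)
  r1 <- render_reference(sc1, opt)
  r2 <- render_reference(sc1, opt, seed_offset = 7L)
  expect_false(identical(r1, r2))
  # empty-scene darkfield minus reference: zero-mean noise (floored residual
  # mean is small relative to the noise level)
  q <- render_quadrants(sc1, opt)
  resid <- q$tl - r1
  expect_lt(abs(mean(resid)), 0.5)
  expect_gt(stats::sd(resid), 1)
})

test_that("sample_population is reproducible and respects its parameters", {
  tmpl <- qdf_scene(c(32, 32))
  p1 <- sample_population(tmpl, n = 2, mass_per_area_range = c(0.1, 1),
                          puncta_per_mass = 0.3, seed = 11)
  p2 <- sample_population(tmpl, n = 2, mass_per_area_range = c(0.1, 1),
                          puncta_per_mass = 0.3, seed = 11)
  expect_identical(p1, p2)
  expect_error(sample_population(tmpl, 5, c(0.4, 0.4), 0.3, 1), "degenerate")

  p0 <- sample_population(tmpl, n = 5, mass_per_area_range = c(0.1, 1),
                          puncta_per_mass = 0, seed = 3)
  expect_true(all(vapply(p0, function(s) nrow(s$puncta), numeric(1)) == 0))

  # ground truth: total puncta amplitude tracks mass (shape-independent
  # organelle density by construction)
  pop <- sample_population(tmpl, n = 300, mass_per_area_range = c(0.1, 1),
                           puncta_per_mass = 0.4, seed = 5)
  gt <- do.call(rbind, lapply(pop, function(s)
    as.data.frame(attr(s, "ground_truth"))))
  expect_gt(pearson_cor(gt$total_amplitude, gt$mass_pg), 0.95)
  # mass per area spans the requested range
  expect_gt(min(gt$mass_per_area), 0.1 - 1e-9)
  expect_lt(max(gt$mass_per_area), 1 + 1e-9)
})
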