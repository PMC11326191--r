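test_that("blank phase yields no labels, with a warning", {
  p <- qdf_phase(matrix(0, 40, 40), 0.532, 0.5)
  expect_warning(labels <- segment_cells(p), "no cells")
  expect_true(all(labels == 0L))
})

test_that("two separated cells are segmented and overlap their ground truth", {
  opt <- test_optics()
  b1 <- qdf_body(20, 20, 10, 2)
  b2 <- qdf_body(55, 55, 8, 2.5)
  sc <- qdf_scene(c(151, 151), bodies = list(b1, b2), phase_noise_sigma = 0.01,
                  seed = 8L)
  ph <- render_phase(sc, opt)
  labels <- segment_cells(ph, min_area = 30)
  expect_equal(max(labels), 2L)
  xs <- (seq_len(151) - 1) * 0.5
  for (b in list(b1, b2)) {
    truth <- sqrt(outer((xs - b$y_um)^2, (xs - b$x_um)^2, `+`)) < b$radius_um
    lab <- labels[truth]
    main <- as.integer(names(which.max(table(lab[lab > 0]))))
    hit <- labels == main
    expect_gt(sum(hit & truth) / sum(truth), 0.95)
  }
})

test_that("touching equal discs are split near the neck", {
  opt <- test_optics()
  # centres 18 um apart, radius 10, domed profiles: two peaks with a saddle
  b1 <- qdf_body(22, 30, 10, 2, roundness = 0.8)   # footprint radius 7.35
  b2 <- qdf_body(36.8, 30, 10, 2, roundness = 0.8) # rims just touching
  sc <- qdf_scene(c(121, 131), bodies = list(b1, b2), phase_noise_sigma = 0)
  ph <- render_phase(sc, opt)
  labels <- segment_cells(ph, min_area = 30, h_depth = 0.1)
  expect_equal(max(labels), 2L)
  # nearest-seed oracle away from the neck: pixels much closer to one centre
  # belong to that centre's label
  xs <- (seq_len(131) - 1) * 0.5; ys <- (seq_len(121) - 1) * 0.5
  d1 <- sqrt(outer((ys - 30)^2, (xs - 22)^2, `+`))
  d2 <- sqrt(outer((ys - 30)^2, (xs - 36.8)^2, `+`))
  l1 <- labels[d1 < 5]; l2 <- labels[d2 < 5]
  expect_equal(length(unique(l1[l1 > 0])), 1L)
  expect_equal(length(unique(l2[l2 > 0])), 1L)
  expect_true(unique(l1[l1 > 0]) != unique(l2[l2 > 0]))
  # both labels reach the neck region around the midline (x ~ 29.4 um)
  neck <- labels[55:67, 56:64]
  expect_true(all(sort(unique(as.vector(neck[neck > 0]))) == 1:2))
})

test_that("labels cover the strong foreground and stay within the weak one", {
  opt <- test_optics()
  sc <- bead_scene(noise = TRUE, seed = 3L)
  ph <- render_phase(sc, opt)
  labels <- segment_cells(ph, min_area = 30)
  sm <- qdfim:::gauss_blur(ph$phase, 1 / 0.5)
  rng <- range(sm)
  norm <- (sm - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  expect_true(all(labels[norm > thr] > 0))
  expect_true(all(norm[labels > 0] > 0.2 * thr))
})

test_that("simple link cases: continuation, cutoff, crossing", {
  det <- data.frame(frame = c(1, 2), label = c(1, 1),
                    x_um = c(0, 1), y_um = c(0, 0.5))
  tr <- link_tracks(det, max_disp = 5)
  expect_equal(unique(tr$track_id), 1L)
  # displacement above the gate: two single-frame tracks
  det2 <- data.frame(frame = c(1, 2), label = c(1, 1),
                     x_um = c(0, 10), y_um = c(0, 0))
  tr2 <- link_tracks(det2, max_disp = 5)
  expect_equal(sort(unique(tr2$track_id)), c(1L, 2L))
  # two particles taking small steps keep identity rather than swapping
  det3 <- data.frame(frame = c(1, 1, 2, 2), label = c(1, 2, 1, 2),
                     x_um = c(0, 10, 1, 9), y_um = 0)
  tr3 <- link_tracks(det3, max_disp = 5)
  t1 <- tr3[tr3$frame == 1, ]; t2 <- tr3[tr3$frame == 2, ]
  expect_equal(t2$track_id[t2$x_um == 1], t1$track_id[t1$x_um == 0])
  expect_equal(t2$track_id[t2$x_um == 9], t1$track_id[t1$x_um == 10])
})

test_that("linking equals the exhaustive-permutation optimum on random instances", {
  set.seed(99)
  for (rep in 1:60) {
    n1 <- sample(0:6, 1); n2 <- sample(0:6, 1)
    p1 <- matrix(runif(2 * n1, 0, 20), ncol = 2)
    p2 <- matrix(runif(2 * n2, 0, 20), ncol = 2)
    det <- rbind(
      if (n1) data.frame(frame = 1, label = seq_len(n1),
                         x_um = p1[, 1], y_um = p1[, 2]),
      if (n2) data.frame(frame = 2, label = seq_len(n2),
                         x_um = p2[, 1], y_um = p2[, 2]))
    if (is.null(det) || nrow(det) == 0) next
    max_disp <- runif(1, 2, 12)
    expect_equal(realized_link_cost(det, max_disp),
                 oracle_link_cost(p1, p2, max_disp),
                 tolerance = 1e-9)
  }
})

test_that("link assignments are invariant to input row order", {
  set.seed(7)
  det <- data.frame(frame = rep(1:3, each = 5), label = rep(1:5, 3),
                    x_um = runif(15, 0, 30), y_um = runif(15, 0, 30))
  tr_a <- link_tracks(det, max_disp = 10)
  shuffled <- det[sample(nrow(det)), ]
  tr_b <- link_tracks(shuffled, max_disp = 10)
  expect_identical(tr_a, tr_b)
})

test_that("memory closes single-frame gaps", {
  det <- data.frame(frame = c(1, 3), label = c(1, 1),
                    x_um = c(0, 1), y_um = 0)
  expect_equal(length(unique(link_tracks(det, 5, memory = 0)$track_id)), 2L)
  expect_equal(length(unique(link_tracks(det, 5, memory = 1)$track_id)), 1L)
})

test_that("debris filtering applies all bounds and reports removals", {
  tab <- data.frame(
    area_um2 = c(10, 120, 300, 80, 200),
    track_length = c(1, 6, 8, 2, 7),
    mean_phase = c(0.05, 0.4, 0.6, 0.3, 0.02),
    mean_df = c(5, 50, 70, 40, 60),
    mean_qdf = c(2, 20, 35, 15, 25))
  # hand count: row 1 fails area & track_length & phase; row 4 fails
  # track_length; row 5 fails phase; rows 2 and 3 survive
  out <- filter_debris(tab, list(area = c(50, NA), track_length = c(3, NA),
                                 mean_phase = c(0.1, 1)))
  expect_equal(nrow(out), 2L)
  expect_equal(out$area_um2, c(120, 300))
  rep <- attr(out, "filter_report")
  expect_equal(rep$removed, c(1L, 1L, 1L))
  # all-pass thresholds are the identity
  out2 <- filter_debris(tab, list(area = c(NA, NA)))
  expect_equal(nrow(out2), 5L)
  # min above every row empties the table
  expect_equal(nrow(filter_debris(tab, list(area = c(1e4, NA)))), 0L)
  expect_error(filter_debris(tab, list(bogus = c(0, 1))), "unknown debris")
})
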