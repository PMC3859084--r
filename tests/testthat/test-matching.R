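test_that("a contour lying exactly on edges scores zero", {
  ct <- as_contour(cbind(c(3, 15, 15, 3), c(3, 3, 12, 12)))
  edges <- matrix(0L, 20, 20)
  pix <- brute_raster(ct)
  edges[cbind(pix[, 2L], pix[, 1L]) + 1L] <- 1L
  df <- distance_field(edges)
  expect_equal(rim_score(ct, df), 0)
})

test_that("a flat contour at constant distance from a line scores it", {
  edges <- matrix(0L, 20, 20); edges[6, ] <- 1L  # edge row y = 5
  df <- distance_field(edges)
  flat <- as_contour(cbind(c(2, 15, 8), c(10, 10, 10)))
  expect_equal(rim_score(flat, df), 5)
})

test_that("rim scoring equals the explicit enumeration oracle", {
  set.seed(31)
  for (rep in 1:8) {
    df <- matrix(runif(400, 0, 9), 20, 20)
    ct <- random_polygon(10L, scale = 6)
    ct <- sweep(ct, 2L, c(9.3, 9.7), "+")
    expect_equal(rim_score(ct, df), brute_rim_score(ct, df),
                 tolerance = 1e-12)
  }
})

test_that("rim scoring is translation-equivariant with the edges", {
  edges <- matrix(0L, 40, 40)
  pix <- brute_raster(circle_contour(6, 32L, c(15, 15)))
  edges[cbind(pix[, 2L], pix[, 1L]) + 1L] <- 1L
  ct <- circle_contour(8, 32L, c(15, 15))
  s1 <- rim_score(ct, distance_field(edges))
  shifted <- matrix(0L, 40, 40)
  shifted[cbind(pix[, 2L] + 7L, pix[, 1L] + 5L) + 1L] <- 1L
  s2 <- rim_score(sweep(ct, 2L, c(5, 7), "+"), distance_field(shifted))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("the true contour beats its translates on its own edge image", {
  truth <- rim_contour(64L, a = 20, b = 14, m = 2, center = c(40, 35))
  edges <- matrix(0L, 70, 80)
  pix <- brute_raster(truth)
  edges[cbind(pix[, 2L], pix[, 1L]) + 1L] <- 1L
  df <- distance_field(edges)
  s0 <- rim_score(truth, df)
  for (off in list(c(2, 0), c(-2, 0), c(0, 2), c(0, -2), c(2, 2), c(-3, 4)))
    expect_lt(s0, rim_score(sweep(truth, 2L, off, "+"), df))
})

test_that("pair scores combine as the arithmetic mean", {
  edges <- matrix(0L, 20, 20); edges[6, ] <- 1L
  df <- distance_field(edges)
  l <- as_contour(cbind(c(2, 15, 8), c(7, 7, 7)))    # score 2
  r <- as_contour(cbind(c(2, 15, 8), c(9, 9, 9)))    # score 4
  sc <- hypothesis_score(l, r, df)
  expect_equal(sc$left, 2); expect_equal(sc$right, 4)
  expect_equal(sc$combined, 3)
  expect_equal(hypothesis_score(r, l, df)$combined, 3)
  expect_equal(hypothesis_score(l, l, df)$combined, rim_score(l, df))
})

test_that("facial fifths anchor on the intercanthal gap", {
  eyes <- eye_region(c(120, 140), c(180, 140),
                     c(100, 130, 140, 150), c(160, 130, 200, 150))
  f <- face_fifths(eyes)
  expect_equal(f$breaks, c(100, 120, 140, 160, 180, 200))
  expect_equal(f$width, 20)
  expect_true(all(diff(f$breaks) == f$width))  # equal contiguous bands
})


test_that("each validation clause flips on a constructed violation", {
  db <- builtin_database()
  eyes <- fixture_eyes()
  roi <- eyeglass_roi(eyes, 1.5)
  fifths <- face_fifths(eyes)
  ok <- validate_hypothesis(make_hyp(db, "elliptic_symmetric",
                                     c(300, 300), 80), eyes, roi, fifths)
  expect_true(ok$ok); expect_identical(ok$reason, "ok")

  # small rim displaced off the eye center: eye no longer enclosed
  v <- validate_hypothesis(make_hyp(db, "elliptic_symmetric",
                                    c(345, 300), 30), eyes, roi, fifths)
  expect_false(v$ok); expect_identical(v$reason, "enclosure")

  # centroid drifts beyond a quarter of the IPD
  v <- validate_hypothesis(make_hyp(db, "elliptic_symmetric",
                                    c(300, 365), 80), eyes, roi, fifths)
  expect_false(v$ok); expect_identical(v$reason, "centroid")

  # rim smaller than the eye rectangle
  v <- validate_hypothesis(make_hyp(db, "elliptic_symmetric",
                                    c(300, 300), 10), eyes, roi, fifths)
  expect_false(v$ok); expect_identical(v$reason, "size")

  # oversized rim spills out of the allowed facial bands
  v <- validate_hypothesis(make_hyp(db, "elliptic_symmetric",
                                    c(300, 300), 200), eyes, roi, fifths)
  expect_false(v$ok); expect_identical(v$reason, "fifths")

  # tight ROI no longer contains the rims
  tight <- eyeglass_roi(eyes, 0.7)
  v <- validate_hypothesis(make_hyp(db, "elliptic_symmetric",
                                    c(300, 300), 80), eyes, tight, fifths)
  expect_false(v$ok); expect_identical(v$reason, "roi")
})

test_that("shrinking a valid rim below the eye rect flips the size clause", {
  db <- builtin_database()
  eyes <- fixture_eyes()
  roi <- eyeglass_roi(eyes, 1.5)
  fifths <- face_fifths(eyes)
  for (s in c(90, 70, 50)) {
    v <- validate_hypothesis(make_hyp(db, "rectangular_symmetric",
                                      c(300, 300), s), eyes, roi, fifths)
    expect_true(v$ok)
  }
  for (s in c(12, 8)) {
    v <- validate_hypothesis(make_hyp(db, "rectangular_symmetric",
                                      c(300, 300), s), eyes, roi, fifths)
    expect_identical(v$reason, "size")
  }
})
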