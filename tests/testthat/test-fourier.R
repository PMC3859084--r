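test_that("c(0) is N times the centroid and |c(1)| encodes circle size", {
  sq <- as_contour(cbind(c(9, 11, 11, 9), c(19, 19, 21, 21)))
  d <- contour_to_descriptors(sq, 4L)
  expect_equal(d$coeffs[d$k == 0L], complex(real = 40, imaginary = 80),
               tolerance = 1e-12)

  circ <- circle_contour(r = 5, n = 64L)
  d <- contour_to_descriptors(circ, 14L)
  expect_equal(Mod(d$coeffs[d$k == 1L]), 320, tolerance = 1e-9)
  expect_true(all(Mod(d$coeffs[!d$k %in% c(0L, 1L)]) < 1e-9))
})

test_that("the DFT satisfies Parseval's identity on random polygons", {
  set.seed(101)
  for (rep in 1:5) {
    ct <- random_polygon(64L)
    z <- complex(real = ct[, 1L], imaginary = ct[, 2L])
    d <- contour_to_descriptors(ct, 64L)
    expect_equal(sum(Mod(z)^2), sum(Mod(d$coeffs)^2) / 64,
                 tolerance = 1e-9)
  }
})

test_that("forward/inverse transforms agree with O(N^2) oracles", {
  set.seed(102)
  for (n in c(16L, 33L, 64L)) {
    ct <- random_polygon(n)
    d <- contour_to_descriptors(ct, n)
    expect_equal(d$coeffs, brute_dft(ct, d$k), tolerance = 1e-9)
    rec <- descriptors_to_contour(d, n)
    expect_equal(unname(rec),
                 unname(brute_inverse(d$coeffs, d$k, n, n)),
                 tolerance = 1e-9)
  }
})

test_that("full round trip is the identity and truncation is monotone", {
  set.seed(103)
  ct <- random_polygon(64L)
  rec <- descriptors_to_contour(contour_to_descriptors(ct, 64L), 64L)
  expect_lt(max_deviation(rec, ct), 1e-9)

  rim <- rim_contour(64L)
  devs <- vapply(c(2L, 6L, 14L, 30L), function(nk)
    max_deviation(descriptors_to_contour(contour_to_descriptors(rim, nk),
                                         64L), rim), 0)
  expect_true(all(diff(devs) <= 1e-12))
})

test_that("keeping only c(0) and c(1) always reconstructs a circle", {
  set.seed(104)
  for (rep in 1:5) {
    ct <- random_polygon(48L, scale = 15)
    rec <- descriptors_to_contour(contour_to_descriptors(ct, 2L), 64L)
    cen <- contour_centroid(ct)
    radii <- sqrt((rec[, 1L] - cen[1L])^2 + (rec[, 2L] - cen[2L])^2)
    expect_lt(max(radii) - min(radii), 1e-6)
  }
})

test_that("normalized descriptors are translation and scale invariant", {
  set.seed(105)
  ct <- rim_contour(64L, center = c(120, 80))
  ref <- normalize_descriptors(contour_to_descriptors(ct, 15L))
  expect_equal(Mod(fetch <- ref$coeffs[ref$k == 1L]), 1, tolerance = 1e-12)
  for (rep in 1:5) {
    delta <- runif(2L, -500, 500)
    alpha <- runif(1L, 0.1, 10)
    moved <- sweep(ct, 2L, delta, "+")
    scaled <- ct * alpha
    for (variant in list(moved, scaled)) {
      d2 <- normalize_descriptors(contour_to_descriptors(variant, 15L))
      expect_equal(d2$coeffs, ref$coeffs, tolerance = 1e-9)
    }
  }
  flat <- as_contour(cbind(c(1, 1, 1), c(1, 1, 1)))
  expect_error(normalize_descriptors(contour_to_descriptors(flat, 3L)),
               "degenerate")
})

test_that("placement inverts normalization and scales linearly", {
  ct <- rim_contour(64L, center = c(50, 60))
  d <- contour_to_descriptors(ct, 15L)
  size0 <- Mod(d$coeffs[d$k == 1L])
  norm <- normalize_descriptors(d)
  back <- descriptors_to_contour(
    place_descriptors(norm, contour_centroid(ct), size0), 64L)
  expect_lt(max_deviation(back, descriptors_to_contour(d, 64L)), 1e-6)

  at0 <- descriptors_to_contour(place_descriptors(norm, c(0, 0), size0), 64L)
  expect_equal(contour_centroid(at0), c(0, 0), tolerance = 1e-9)

  s1 <- descriptors_to_contour(place_descriptors(norm, c(0, 0), 100), 64L)
  s2 <- descriptors_to_contour(place_descriptors(norm, c(0, 0), 200), 64L)
  expect_equal(unname(s2), unname(2 * s1), tolerance = 1e-9)
  expect_error(place_descriptors(norm, c(0, 0), -1), "positive")
})

test_that("morphing is a coefficient-wise convex combination", {
  d1 <- normalize_descriptors(contour_to_descriptors(rim_contour(64L), 15L))
  d2 <- normalize_descriptors(contour_to_descriptors(
    rim_contour(64L, a = 30, b = 28, m = 2), 15L))
  expect_equal(morph_descriptors(d1, d2, 1)$coeffs, d1$coeffs)
  expect_equal(morph_descriptors(d1, d2, 0)$coeffs, d2$coeffs)
  for (b in c(0, 0.3, 0.77, 1))
    expect_equal(morph_descriptors(d1, d1, b)$coeffs, d1$coeffs)
  mid <- morph_descriptors(d1, d2, 0.5)
  expect_equal(mid$coeffs, 0.5 * d1$coeffs + 0.5 * d2$coeffs)
  expect_error(morph_descriptors(d1, d2, 1.2), "beta")
  d3 <- normalize_descriptors(contour_to_descriptors(rim_contour(64L), 11L))
  expect_error(morph_descriptors(d1, d3, 0.5), "index")
})

test_that("reconstructed morphs vary continuously in beta", {
  d1 <- normalize_descriptors(contour_to_descriptors(rim_contour(64L), 15L))
  d2 <- normalize_descriptors(contour_to_descriptors(
    rim_contour(64L, a = 28, b = 26, m = 2), 15L))
  betas <- seq(0, 1, by = 0.05)
  recs <- lapply(betas, function(b)
    descriptors_to_contour(morph_descriptors(d1, d2, b), 64L))
  steps <- vapply(seq_len(length(recs) - 1L), function(i)
    max_deviation(recs[[i]], recs[[i + 1L]]), 0)
  expect_true(all(steps < 0.05 * max_deviation(recs[[1L]],
                                               recs[[length(recs)]]) + 1e-9))
})

test_that("horizontal flip mirrors the point set and is an involution", {
  # mirrored reconstruction: x -> 2 cx - x with y unchanged, as point sets
  asym <- published_rim_fixtures()$sample_asymmetric
  rec <- descriptors_to_contour(asym, 64L)
  cen <- contour_centroid(rec)
  flipped <- descriptors_to_contour(hflip_descriptors(asym), 64L)
  mirrored <- cbind(2 * cen[1L] - rec[, 1L], rec[, 2L])
  # traversal order may reverse: match nearest points
  d <- vapply(seq_len(64L), function(i)
    min(sqrt((flipped[, 1L] - mirrored[i, 1L])^2 +
             (flipped[, 2L] - mirrored[i, 2L])^2)), 0)
  expect_lt(max(d), 1e-6)

  twice <- descriptors_to_contour(hflip_descriptors(hflip_descriptors(asym)),
                                  64L)
  d2 <- vapply(seq_len(64L), function(i)
    min(sqrt((twice[, 1L] - rec[i, 1L])^2 +
             (twice[, 2L] - rec[i, 2L])^2)), 0)
  expect_lt(max(d2), 1e-6)

  circ <- contour_to_descriptors(circle_contour(10, 64L, c(30, 40)), 15L)
  fc <- descriptors_to_contour(hflip_descriptors(circ), 64L)
  radii <- sqrt((fc[, 1L] - 30)^2 + (fc[, 2L] - 40)^2)
  expect_equal(radii, rep(10, 64L), tolerance = 1e-9)
})

test_that("descriptor sets serialize losslessly through JSON", {
  d <- normalize_descriptors(contour_to_descriptors(rim_contour(64L), 15L))
  d2 <- descriptors_from_json(descriptors_to_json(d))
  expect_equal(d2$coeffs, d$coeffs, tolerance = 1e-12)
  expect_identical(d2$k, d$k)
  expect_identical(d2$n_points, d$n_points)
  expect_true(d2$normalized)
})

test_that("degenerate inputs are rejected", {
  expect_error(as_contour(cbind(1:2, 1:2)), "at least 3")
  expect_error(as_contour(cbind(c(1, 2, NA), 1:3)), "finite")
  expect_error(contour_to_descriptors(circle_contour(1, 8L), 1L), "at least 2")
  expect_error(contour_to_descriptors(circle_contour(1, 8L), 9L), "exceed")
  d <- contour_to_descriptors(circle_contour(1, 8L), 4L)
  expect_error(descriptors_to_contour(d, 2L), "at least 3")
})
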