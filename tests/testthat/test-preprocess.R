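fake_detector <- function(rects) {
  function(image) do.call(rbind, lapply(rects, function(r)
    data.frame(x0 = r[1L], y0 = r[2L], x1 = r[1L] + r[3L],
               y1 = r[2L] + r[4L])))
}
blank <- matrix(200, 240, 360)

test_that("candidate grouping yields the hand-derived eye region", {
  det <- fake_detector(list(c(100, 100, 20, 12), c(220, 102, 20, 12)))
  eyes <- detect_eyes(blank, det)
  expect_equal(eyes$left_center, c(110, 106))
  expect_equal(eyes$right_center, c(230, 108))
  expect_equal(eyes$ipd, sqrt(120^2 + 2^2), tolerance = 1e-9)
})

test_that("candidates without an opposite-side partner are discarded", {
  det <- fake_detector(list(c(100, 100, 20, 12), c(220, 102, 20, 12),
                            c(150, 160, 20, 12)))  # far below: no partner
  eyes <- detect_eyes(blank, det)
  expect_equal(eyes$left_center, c(110, 106))
  expect_equal(eyes$right_center, c(230, 108))
})

test_that("overlapping zones merge into their enclosing rectangle", {
  det <- fake_detector(list(c(100, 100, 20, 12), c(106, 102, 20, 12),
                            c(220, 101, 20, 12)))
  eyes <- detect_eyes(blank, det)
  # left side: two overlapping zones -> one enclosing rect (100..126, 100..114)
  expect_equal(eyes$left_center, c(113, 107))
})

test_that("excessive inter-eye slope is rejected", {
  det <- fake_detector(list(c(100, 100, 20, 20), c(220, 135, 20, 20)))
  expect_error(detect_eyes(blank, det), "slope")
  det1 <- fake_detector(list(c(100, 100, 20, 12)))
  expect_error(detect_eyes(blank, det1), "fewer than two")
})

test_that("interpupillary distance is the Euclidean center distance", {
  e <- eye_region(c(0, 0), c(3, 4), c(-1, -1, 1, 1), c(2, 3, 4, 5))
  expect_equal(interpupillary_distance(e), 5)
  e2 <- eye_region(c(10, 7), c(13, 11), c(9, 6, 11, 8), c(12, 10, 14, 12))
  expect_equal(interpupillary_distance(e2), 5)  # joint translation
  expect_error(eye_region(c(5, 0), c(3, 4), c(4, -1, 6, 1), c(2, 3, 4, 5)),
               "left of")
})

test_that("the eyeglasses ROI has the decided geometry", {
  e <- supplied_eyes(c(100, 200), c(200, 200))
  r <- eyeglass_roi(e, 1.5)
  expect_equal(unname(r[1:4]), c(150 - 125, 200 - 75, 150 + 125, 200 + 75))
  # monotone in delta before clipping
  r_small <- eyeglass_roi(e, 0.8)
  expect_true(all(r_small[1:2] >= r[1:2]) && all(r_small[3:4] <= r[3:4]))
  expect_error(eyeglass_roi(e, 0), "positive")
  # clipping must keep the eye rects inside
  expect_error(eyeglass_roi(e, 1.5, dim = c(205, 300)), "eye rectangles")
})

test_that("Canny behaves canonically on flat and step images", {
  expect_error(distance_field(edge_map(matrix(7, 40, 40))), "empty edge map")
  step <- cbind(matrix(0, 40, 20), matrix(255, 40, 20))
  em <- edge_map(step, sigma = 1)
  cols <- unique(which(em == 1L, arr.ind = TRUE)[, 2L])
  expect_lte(length(cols), 2L)           # a thin vertical line
  expect_true(all(abs(cols - 20.5) < 3)) # at the step
  rows <- unique(which(em == 1L, arr.ind = TRUE)[, 1L])
  expect_gte(length(rows), 30L)          # spanning most of the height
  expect_error(edge_map(step, low = 10, high = 5), "thresholds")
})

test_that("a clean rendered rim is fully supported by nearby edges", {
  db <- builtin_database()
  sc <- generate_scene(scene_spec(noise_sigma = 0, seed = 5), db)
  em <- edge_map(sc$image)
  df <- distance_field(em)
  pix <- brute_raster(sc$truth$left)
  d <- df[cbind(pix[, 2L], pix[, 1L]) + 1L]
  expect_gte(mean(d <= 2.2), 0.9)   # flanks within ~1.3 px, corners ~3 px
  expect_lt(mean(d), 1.6)
  expect_gt(edges_near_contour(em, sc$truth$left, tol = 2.5), 300)
})

test_that("the distance field matches the brute-force oracle exactly", {
  e <- matrix(0L, 11, 11); e[6, 6] <- 1L
  df <- distance_field(e)
  expect_equal(df[1, 1], sqrt(50), tolerance = 1e-9)
  expect_true(all(distance_field(matrix(1L, 5, 5)) == 0))
  set.seed(21)
  for (rep in 1:5) {
    e <- matrix(0L, 20, 20)
    e[sample(400, sample(3:30, 1))] <- 1L
    df <- distance_field(e)
    expect_equal(df, brute_distance_field(e), tolerance = 1e-9)
    # 1-Lipschitz between 8-neighbors
    dmax <- max(abs(diff(df)), abs(t(diff(t(df)))),
                abs(df[-1, -1] - df[-20, -20]), abs(df[-1, -20] - df[-20, -1]))
    expect_lte(dmax, sqrt(2) + 1e-9)
  }
})

test_that("PGM images load in both plain and raw variants", {
  m <- matrix(as.double(0:249 %% 251), 10, 25)
  p2 <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "25 10", "255",
               paste(as.integer(t(m)), collapse = " ")), p2)
  expect_equal(load_image(p2), m, tolerance = 1e-9)
  p5 <- withr::local_tempfile(fileext = ".pgm")
  con <- file(p5, "wb")
  writeChar("P5\n25 10\n255\n", con, eos = NULL)
  writeBin(as.raw(as.integer(t(m))), con)
  close(con)
  expect_equal(load_image(p5), m, tolerance = 1e-9)
})

test_that("supplied eye centers build a consistent region", {
  e <- supplied_eyes(c(120, 220), c(320, 224))
  expect_equal(e$ipd, sqrt(200^2 + 4^2))
  expect_true(e$left_rect[1L] < 120 && e$left_rect[3L] > 120)
})
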