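# fabricate a scored hypothesis with a prescribed bounding box
stub_hyp <- function(db, bbox, score, gen_idx = 1L) {
  h <- make_hyp(db, "elliptic_symmetric", c(300, 300), 80,
                gen_idx = gen_idx)
  h$bbox <- bbox
  h$score <- lenstrace:::match_score(score, score)
  h
}

test_that("hypothesis sampling respects the uniform domain", {
  db <- builtin_database()
  eyes <- fixture_eyes()
  cfg <- lens_config()
  set.seed(41)
  hyps <- lapply(1:4000, function(i)
    sample_hypothesis("asymmetric", eyes, db, cfg, gen_idx = i))
  lc <- t(vapply(hyps, function(h) h$left$centroid, numeric(2L)))
  sizes <- vapply(hyps, function(h) h$left$size, 0)
  betas <- vapply(hyps, function(h) h$left$beta, 0)
  rcx <- vapply(hyps, function(h) h$right_centroid[1L], 0)
  box <- 0.25 * eyes$ipd
  expect_true(all(abs(lc[, 1L] - 300) <= box & abs(lc[, 2L] - 300) <= box))
  expect_true(all(abs(rcx - 500) <= box))
  expect_true(all(sizes >= 0.35 * eyes$ipd & sizes <= 0.70 * eyes$ipd))
  expect_true(all(betas >= 0 & betas <= 1))
  # right y is tied to the left centroid's y
  rcy <- vapply(hyps, function(h) h$right_centroid[2L], 0)
  expect_equal(rcy, lc[, 2L])
  # empirical mean size within 3 sigma of the uniform mean 0.525 ipd
  se <- 0.35 / sqrt(12) * eyes$ipd / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 0.525 * eyes$ipd), 3 * se)
})

test_that("sampling replays identically under a fixed seed", {
  db <- builtin_database()
  eyes <- fixture_eyes()
  cfg <- lens_config()
  draw <- function() {
    set.seed(77)
    lapply(1:20, function(i) sample_hypothesis("rectangular_symmetric",
                                               eyes, db, cfg))
  }
  h1 <- draw(); h2 <- draw()
  expect_identical(
    lapply(h1, function(h) h[c("left", "right_centroid")]),
    lapply(h2, function(h) h[c("left", "right_centroid")]))
})

test_that("rectangle overlap fraction uses the smaller-area denominator", {
  expect_equal(rect_overlap_fraction(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(rect_overlap_fraction(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(rect_overlap_fraction(c(0, 0, 10, 10), c(1, 0, 11, 10)), 0.9)
  expect_equal(rect_overlap_fraction(c(0, 0, 20, 20), c(5, 5, 15, 15)), 1)
  expect_error(rect_overlap_fraction(c(0, 0, 0, 10), c(0, 0, 1, 1)),
               "zero-area")
})

test_that("clustering merges duplicates and separates disjoint boxes", {
  db <- builtin_database()
  same <- lapply(1:6, function(i) stub_hyp(db, c(0, 0, 10, 10), 1, i))
  cl <- cluster_hypotheses(same, 0.9)
  expect_length(cl, 1L)
  expect_length(cl[[1L]]$members, 6L)

  two <- list(stub_hyp(db, c(0, 0, 10, 10), 1, 1L),
              stub_hyp(db, c(50, 50, 60, 60), 2, 2L))
  cl <- cluster_hypotheses(two, 0.9)
  expect_length(cl, 2L)
  expect_error(cluster_hypotheses(list(), 0.9), "empty")
})

test_that("the traced three-hypothesis merge sequence is reproduced", {
  db <- builtin_database()
  A <- stub_hyp(db, c(0, 0, 10, 10), 1.0, 1L)
  B <- stub_hyp(db, c(0, 0.5, 10, 10.5), 1.2, 2L)  # 0.95 overlap with A
  C <- stub_hyp(db, c(5, 0, 15, 10), 0.8, 3L)      # 0.5 with both
  cl <- cluster_hypotheses(list(A, B, C), 0.9)
  sizes <- sort(vapply(cl, function(c) length(c$members), 0L))
  expect_equal(sizes, c(1L, 2L))
  ab <- cl[[which(vapply(cl, function(c) length(c$members), 0L) == 2L)]]
  expect_setequal(vapply(ab$members, `[[`, 0L, "gen_idx"), c(1L, 2L))
  expect_equal(ab$cluster_score, 1.1)
})

test_that("clustering partitions its input deterministically", {
  db <- builtin_database()
  set.seed(42)
  hyps <- lapply(1:60, function(i) {
    x <- runif(1, 0, 100); y <- runif(1, 0, 100)
    stub_hyp(db, c(x, y, x + runif(1, 5, 15), y + runif(1, 5, 15)),
             runif(1, 0.5, 3), i)
  })
  cl1 <- cluster_hypotheses(hyps, 0.9)
  cl2 <- cluster_hypotheses(hyps, 0.9)
  members <- function(cl) lapply(cl, function(c)
    vapply(c$members, `[[`, 0L, "gen_idx"))
  expect_identical(members(cl1), members(cl2))
  all_idx <- sort(unlist(members(cl1)))
  expect_identical(all_idx, 1:60)  # each hypothesis in exactly one cluster
  for (c in cl1)
    for (m in c$members)
      expect_true(all(m$bbox >= c$bbox[c(1, 2, 1, 2)] - 1e-9) &&
                  all(m$bbox <= c$bbox[c(3, 4, 3, 4)] + 1e-9))
})

test_that("selection is cluster-first, then best member, then earliest", {
  db <- builtin_database()
  # cluster A: mean 1.0 but its best member is mediocre; cluster B holds
  # the single best-scoring hypothesis overall yet a worse mean
  A <- lapply(seq_along(sa <- c(0.7, 0.9, 1.4)), function(i)
    stub_hyp(db, c(0, 0, 10, 10), sa[i], i))
  B <- lapply(seq_along(sb <- c(0.5, 3.5)), function(i)
    stub_hyp(db, c(50, 0, 60, 10), sb[i], 10L + i))
  cl <- cluster_hypotheses(c(A, B), 0.9)
  best <- select_best(cl)
  expect_equal(best$score$combined, 0.7)
  expect_equal(best$gen_idx, 1L)

  ties <- lapply(1:4, function(i) stub_hyp(db, c(0, 0, 10, 10), 2.0, 5L - i))
  expect_equal(select_best(cluster_hypotheses(ties, 0.9))$gen_idx, 1L)
  expect_error(select_best(list()), "no clusters")
})

test_that("Monte Carlo search keeps only valid, scored hypotheses", {
  db <- builtin_database()
  spec <- scene_spec(cls = "elliptic_symmetric", seed = 9, noise_sigma = 0)
  sc <- generate_scene(spec, db)
  eyes <- detect_eyes(sc$image)
  roi <- eyeglass_roi(eyes, 1.5, dim(sc$image))
  df <- distance_field(edge_map(sc$image, roi = roi))
  fifths <- face_fifths(eyes)
  cfg <- lens_config(search.max_hypotheses = 2000L)
  set.seed(1)
  hyps <- monte_carlo_search(df, eyes, roi, fifths, db,
                             "elliptic_symmetric", cfg)
  expect_gt(length(hyps), 0L)
  scores <- vapply(hyps, function(h) h$score$combined, 0)
  expect_lt(min(scores), 3.0)  # a near-true sample fits the clean rims
  expect_lt(min(scores), 0.5 * median(scores))
  for (h in hyps[seq_len(min(25L, length(hyps)))])
    expect_true(validate_hypothesis(h, eyes, roi, fifths)$ok)
})

test_that("an off-face decoy contour never wins the selection", {
  db <- builtin_database()
  for (s in 1:8) {
    spec <- random_scene_spec(db, seed = 500 + s, decoy = TRUE)
    sc <- generate_scene(spec, db)
    cfg <- lens_config(seed = 900 + s, search.max_hypotheses = 1500L,
                       refine.max_iterations = 30L)
    res <- extract_lenses(sc$image, db, cfg)
    # a decoy-locked solution would share no area with the true lenses
    expect_gt(overlap_fraction(res$left_contour, sc$truth$left), 0.5)
    expect_gt(overlap_fraction(res$right_contour, sc$truth$right), 0.5)
  }
})
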