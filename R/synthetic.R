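#' Specification of a synthetic facial scene
#'
#' Describes everything needed to render a deterministic test image: two
#' eye positions, a lens model (class, reference shape pair, morph
#' factor, size, centroids), the fraction of each rim boundary erased,
#' clutter flags, noise level and the seed driving all randomness in the
#' rendering.
#'
#' @param dim image dimensions `c(height, width)` in pixels.
#' @param eye_left,eye_right eye center coordinates `c(x, y)`.
#' @param cls rim shape class.
#' @param s1_id,s2_id database ids of the reference shapes.
#' @param beta morph factor in `[0, 1]`.
#' @param size lens size in pixels (first-harmonic radius scale).
#' @param left_centroid,right_centroid lens centers; default mirror
#'   placement on the eye centers.
#' @param gap_fraction fraction of each rim boundary erased, in `[0, 1)`.
#' @param eyebrows,nose,specular,decoy clutter flags: eyebrow arcs, a nose
#'   line, bright blobs inside the lenses, an off-face closed decoy
#'   contour.
#' @param noise_sigma Gaussian intensity noise standard deviation
#'   (intensity units on the 0-255 scale).
#' @param seed integer seed for gap placement, clutter jitter and noise.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(dim = c(600L, 800L),
                       eye_left = c(300, 300), eye_right = c(500, 300),
                       cls = "elliptic_symmetric",
                       s1_id = "ellip_03", s2_id = "ellip_07", beta = 0.5,
                       size = NULL,
                       left_centroid = NULL, right_centroid = NULL,
                       gap_fraction = 0, eyebrows = FALSE, nose = FALSE,
                       specular = FALSE, decoy = FALSE,
                       noise_sigma = 4, seed = 1L) {
  ipd <- sqrt(sum((eye_right - eye_left)^2))
  if (is.null(size)) size <- 0.42 * ipd
  if (is.null(left_centroid)) left_centroid <- eye_left
  if (is.null(right_centroid))
    right_centroid <- c(eye_left[1L] + eye_right[1L] - left_centroid[1L],
                        left_centroid[2L])
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must lie in [0, 1)")
  spec <- structure(list(
    dim = as.integer(dim), eye_left = eye_left, eye_right = eye_right,
    cls = cls, s1_id = s1_id, s2_id = s2_id, beta = beta, size = size,
    left_centroid = left_centroid, right_centroid = right_centroid,
    gap_fraction = gap_fraction, eyebrows = eyebrows, nose = nose,
    specular = specular, decoy = decoy, noise_sigma = noise_sigma,
    seed = as.integer(seed)), class = "scene_spec")
  spec
}

scene_truth_hypothesis <- function(spec, db) {
  glasses_hypothesis(spec$cls, spec$left_centroid, spec$size,
                     db_find(db, spec$s1_id), db_find(db, spec$s2_id),
                     spec$beta, spec$right_centroid)
}

#' Render a synthetic scene
#'
#' Draws a flat light background with dark eye blobs, anti-aliased rim
#' strokes reconstructed from the spec's morphed and placed descriptors
#' (the right rim being the mirrored left shape), optional eyebrow arcs,
#' nose line, specular blobs and decoy contour, erases `gap_fraction` of
#' each rim boundary in contiguous arcs, and adds Gaussian intensity
#' noise. Identical specs render bit-identical images.
#'
#' @param spec a `scene_spec`.
#' @param db the `shape_database` the spec's ids refer to.
#' @return list with `image` (intensity matrix) and `truth` (class
#'   `ground_truth`: exact 64-point `left` / `right` contours, eye
#'   centers, `ipd`, `cls`).
#' @export
generate_scene <- function(spec, db = builtin_database()) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$dim[1L]; w <- spec$dim[2L]
  ipd <- sqrt(sum((spec$eye_right - spec$eye_left)^2))
  hyp <- scene_truth_hypothesis(spec, db)
  truth_ct <- hypothesis_contours(hyp, 64L)
  bb <- rect_union(contour_bbox(truth_ct$left), contour_bbox(truth_ct$right))
  if (bb[1L] < 0 || bb[2L] < 0 || bb[3L] > w - 1 || bb[4L] > h - 1)
    stop("inconsistent scene spec: lens contours fall outside the image")

  set.seed(spec$seed)
  img <- matrix(200, h, w)
  compose <- function(img, cov, value)
    img * (1 - cov) + value * cov

  # eye blobs (dark filled ellipses)
  for (ec in list(spec$eye_left, spec$eye_right))
    img <- compose(img, cpp_ellipse_coverage(ec[1L], ec[2L],
                                             0.07 * ipd, 0.045 * ipd, w, h),
                   30)

  # rim strokes with gaps
  render_ct <- hypothesis_contours(hyp, 256L)
  for (ct in render_ct) {
    segs <- contour_segments(ct)
    keep <- gap_keep_mask(nrow(segs), spec$gap_fraction)
    img <- compose(img,
                   cpp_stroke_coverage(segs[keep, , drop = FALSE], w, h, 2),
                   40)
  }

  if (spec$eyebrows) {
    for (ec in list(spec$eye_left, spec$eye_right)) {
      t <- seq(0, 1, length.out = 40L)
      bx <- ec[1L] + (t - 0.5) * 0.55 * ipd + runif(1L, -3, 3)
      by <- ec[2L] - 0.42 * ipd - 0.07 * ipd * sin(pi * t) + runif(1L, -3, 3)
      img <- compose(img, cpp_stroke_coverage(
        cbind(bx[-length(bx)], by[-length(by)], bx[-1L], by[-1L]),
        w, h, 3), 60)
    }
  }
  if (spec$nose) {
    mx <- (spec$eye_left[1L] + spec$eye_right[1L]) / 2
    my <- (spec$eye_left[2L] + spec$eye_right[2L]) / 2
    img <- compose(img, cpp_stroke_coverage(
      matrix(c(mx, my + 0.15 * ipd, mx, my + 0.6 * ipd), 1L), w, h, 2), 90)
  }
  if (spec$specular) {
    for (ec in list(spec$eye_left, spec$eye_right))
      for (r in 1:2) {
        off <- runif(2L, -0.12, 0.12) * ipd
        img <- compose(img, cpp_ellipse_coverage(
          ec[1L] + off[1L], ec[2L] + off[2L], runif(1L, 3, 6),
          runif(1L, 2, 4), w, h), 255)
      }
  }
  if (spec$decoy) {
    mx <- (spec$eye_left[1L] + spec$eye_right[1L]) / 2
    my <- (spec$eye_left[2L] + spec$eye_right[2L]) / 2
    dct <- superellipse_contour(0.16 * ipd, 0.12 * ipd, 2.5, n_out = 64L)
    dct <- sweep(dct, 2L, c(mx, my + 0.6 * ipd), "+")
    img <- compose(img, cpp_stroke_coverage(contour_segments(dct), w, h, 2),
                   40)
  }

  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
  img <- pmin(pmax(img, 0), 255)

  truth <- structure(list(left = truth_ct$left, right = truth_ct$right,
                          eye_left = spec$eye_left,
                          eye_right = spec$eye_right,
                          ipd = ipd, cls = spec$cls),
                     class = "ground_truth")
  list(image = img, truth = truth)
}

contour_segments <- function(ct) {
  n <- nrow(ct)
  j <- c(2:n, 1L)
  cbind(ct[, 1L], ct[, 2L], ct[j, 1L], ct[j, 2L])
}

# logical keep-mask over m boundary segments with `gap_fraction` of them
# erased in up to 3 contiguous arcs at random positions
gap_keep_mask <- function(m, gap_fraction) {
  keep <- rep(TRUE, m)
  if (gap_fraction <= 0) return(keep)
  n_gaps <- 3L
  per <- round(gap_fraction * m / n_gaps)
  if (per < 1L) { n_gaps <- 1L; per <- max(1L, round(gap_fraction * m)) }
  starts <- sample.int(m, n_gaps)
  for (s in starts)
    keep[((s - 1L + seq_len(per) - 1L) %% m) + 1L] <- FALSE
  keep
}

#' Overlap fraction of a detected contour with the true contour
#'
#' Rasterizes both closed contours and returns
#' `area(detected interior intersect truth interior) / area(truth
#' interior)` — the true-positive criterion compares this against
#' `gamma = 0.95`. The denominator is always the truth area, so the
#' measure is not symmetric in its arguments.
#'
#' @param detected,truth closed contour matrices.
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(detected, truth) {
  detected <- as_contour(detected); truth <- as_contour(truth)
  bb <- rect_union(contour_bbox(detected), contour_bbox(truth))
  ox <- floor(bb[1L]) - 1; oy <- floor(bb[2L]) - 1
  w <- ceiling(bb[3L]) - ox + 2; h <- ceiling(bb[4L]) - oy + 2
  dm <- cpp_fill_polygon(detected[, 1L] - ox, detected[, 2L] - oy, w, h)
  tm <- cpp_fill_polygon(truth[, 1L] - ox, truth[, 2L] - oy, w, h)
  ta <- sum(tm)
  if (ta == 0) stop("degenerate truth contour: empty interior")
  sum(dm & tm) / ta
}

#' Intersection-over-union of two closed contours
#'
#' Symmetric companion diagnostic to [overlap_fraction()]: a grossly
#' oversized detection can still cover the truth area, but its IoU drops.
#'
#' @inheritParams overlap_fraction
#' @return IoU in `[0, 1]`.
#' @export
contour_iou <- function(detected, truth) {
  detected <- as_contour(detected); truth <- as_contour(truth)
  bb <- rect_union(contour_bbox(detected), contour_bbox(truth))
  ox <- floor(bb[1L]) - 1; oy <- floor(bb[2L]) - 1
  w <- ceiling(bb[3L]) - ox + 2; h <- ceiling(bb[4L]) - oy + 2
  dm <- cpp_fill_polygon(detected[, 1L] - ox, detected[, 2L] - oy, w, h)
  tm <- cpp_fill_polygon(truth[, 1L] - ox, truth[, 2L] - oy, w, h)
  un <- sum(dm | tm)
  if (un == 0) stop("degenerate contours: empty union")
  sum(dm & tm) / un
}

#' Draw a random scene specification
#'
#' Samples realistic study conditions around a nominal frontal portrait:
#' 800 x 600 image, interpupillary distance 180-220 px, small eye-level
#' jitter and tilt (well under the 10 degree gate), lens size 0.38-0.46
#' of the IPD, lens centroids within 0.08 IPD of the eye centers, a
#' uniformly chosen class and same-class reference pair, uniform morph
#' factor.
#'
#' @param db a `shape_database`.
#' @param cls rim class, or `NULL` to choose uniformly.
#' @param seed scene seed (also stored in the spec).
#' @param gap_fraction,eyebrows,nose,specular,decoy,noise_sigma passed to
#'   [scene_spec()].
#' @return a `scene_spec`.
#' @export
random_scene_spec <- function(db = builtin_database(), cls = NULL,
                              seed = 1L, gap_fraction = 0,
                              eyebrows = FALSE, nose = FALSE,
                              specular = FALSE, decoy = FALSE,
                              noise_sigma = 4) {
  set.seed(seed)
  if (is.null(cls)) cls <- sample(shape_classes(), 1L)
  ipd <- runif(1L, 180, 220)
  midx <- 400 + runif(1L, -15, 15)
  midy <- 300 + runif(1L, -15, 15)
  dy <- runif(1L, -0.02, 0.02) * ipd  # slight head tilt
  eye_left <- c(midx - ipd / 2, midy - dy / 2)
  eye_right <- c(midx + ipd / 2, midy + dy / 2)
  idx <- which(db_entry_classes(db) == cls)
  pick <- idx[sample.int(length(idx), 2L, replace = TRUE)]
  off <- runif(2L, -0.08, 0.08) * ipd
  scene_spec(dim = c(600L, 800L), eye_left = eye_left,
             eye_right = eye_right, cls = cls,
             s1_id = db_entry_ids(db)[pick[1L]],
             s2_id = db_entry_ids(db)[pick[2L]],
             beta = runif(1L), size = runif(1L, 0.38, 0.46) * ipd,
             left_centroid = eye_left + off,
             gap_fraction = gap_fraction, eyebrows = eyebrows, nose = nose,
             specular = specular, decoy = decoy,
             noise_sigma = noise_sigma, seed = seed)
}

#' Standard fixture batteries
#'
#' Named families of seeded scene specs used by the benchmark and the
#' test suite: `"clean"` (no clutter, no gaps), `"cluttered"` (eyebrow
#' arcs, nose line and 20% boundary gaps) and `"decoy"` (clean plus an
#' off-face closed decoy contour).
#'
#' @param name battery name.
#' @param n number of scenes.
#' @param seed base seed; scene i uses `seed + i`.
#' @param db a `shape_database`.
#' @return list of `scene_spec`s.
#' @export
scene_battery <- function(name = c("clean", "cluttered", "decoy"), n = 50L,
                          seed = 1L, db = builtin_database()) {
  name <- match.arg(name)
  lapply(seq_len(n), function(i) {
    s <- seed + i
    switch(name,
      clean = random_scene_spec(db, seed = s),
      cluttered = random_scene_spec(db, seed = s, gap_fraction = 0.2,
                                    eyebrows = TRUE, nose = TRUE),
      decoy = random_scene_spec(db, seed = s, decoy = TRUE))
  })
}
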