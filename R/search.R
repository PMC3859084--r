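#' Glasses hypothesis
#'
#' A candidate pair of rims. The left rim is described by the model vector
#' (shape class, centroid, size, two same-class reference shapes and the
#' morph factor `beta`: the shape is `beta * S1 + (1 - beta) * S2` in
#' descriptor space). The right rim is always the horizontal mirror of the
#' left rim's shape at the same size; only its centroid is a free
#' parameter (x sampled independently, y tied to the left centroid under
#' the near-horizontal-frame assumption).
#'
#' `size` is in pixels on the first-harmonic radius scale: a circular rim
#' of radius `r` pixels has size `r`.
#'
#' @param cls shape class label.
#' @param centroid,right_centroid length-2 centers of the two lenses.
#' @param size lens size in pixels.
#' @param s1,s2 database entries (lists with `id` and normalized `desc`).
#' @param beta morph factor in `[0, 1]`.
#' @param gen_idx generation index used for deterministic tie-breaking.
#' @return object of class `glasses_hypothesis`.
#' @export
glasses_hypothesis <- function(cls, centroid, size, s1, s2, beta,
                               right_centroid, gen_idx = NA_integer_) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  if (size <= 0) stop("size must be positive")
  structure(list(
    cls = cls,
    left = list(centroid = as.numeric(centroid), size = size,
                s1_id = s1$id, s2_id = s2$id, beta = beta),
    right_centroid = as.numeric(right_centroid),
    s1_coeffs = s1$desc$coeffs, s2_coeffs = s2$desc$coeffs,
    k = s1$desc$k, n_points = s1$desc$n_points,
    score = NULL, gen_idx = gen_idx
  ), class = "glasses_hypothesis")
}

#' @export
print.glasses_hypothesis <- function(x, ...) {
  cat(sprintf(
    "<glasses_hypothesis: %s, left (%.1f, %.1f), size %.1f px, beta %.2f%s>\n",
    x$cls, x$left$centroid[1L], x$left$centroid[2L], x$left$size,
    x$left$beta,
    if (is.null(x$score)) "" else sprintf(", score %.3f", x$score$combined)))
  invisible(x)
}

# morphed normalized coefficients of the left rim
hypothesis_norm_coeffs <- function(hyp) {
  hyp$left$beta * hyp$s1_coeffs + (1 - hyp$left$beta) * hyp$s2_coeffs
}

#' Reconstruct the left and right rim contours of a hypothesis
#'
#' @param hyp a `glasses_hypothesis`.
#' @param n_points reconstruction point count.
#' @return list with contour matrices `left` and `right`.
#' @export
hypothesis_contours <- function(hyp, n_points = 64L) {
  stopifnot(inherits(hyp, "glasses_hypothesis"))
  cm <- hypothesis_norm_coeffs(hyp)
  norm <- descriptor_set(cm, hyp$k, hyp$n_points, normalized = TRUE)
  scale <- hyp$left$size * hyp$n_points  # pixel size -> raw |c(1)|
  left <- descriptors_to_contour(
    place_descriptors(norm, hyp$left$centroid, scale), n_points)
  right <- descriptors_to_contour(
    place_descriptors(hflip_descriptors(norm), hyp$right_centroid, scale),
    n_points)
  list(left = left, right = right)
}

hypothesis_bbox <- function(hyp) {
  ct <- hypothesis_contours(hyp)
  rect_union(contour_bbox(ct$left), contour_bbox(ct$right))
}

rect_union <- function(a, b) {
  c(min(a[1L], b[1L]), min(a[2L], b[2L]), max(a[3L], b[3L]), max(a[4L], b[4L]))
}

#' Draw one glasses hypothesis uniformly from the search domain
#'
#' The left centroid is uniform in an axis-aligned box of half-width
#' `search.centroid_box_ipd * ipd` around the left eye center; the size is
#' uniform in `[search.size_min_ipd, search.size_max_ipd] * ipd`; the two
#' reference shapes come from [sample_shape_pair()]; `beta` is uniform in
#' `[0, 1]`. The right centroid's x-offset is drawn independently from the
#' mirrored distribution around the right eye center; its y equals the
#' left centroid's y.
#'
#' @param cls shape class to sample from.
#' @param eyes an `eye_region`.
#' @param db a `shape_database`.
#' @param cfg a [lens_config()].
#' @param gen_idx generation index recorded on the hypothesis.
#' @return an unscored `glasses_hypothesis`.
#' @export
sample_hypothesis <- function(cls, eyes, db, cfg = lens_config(),
                              gen_idx = NA_integer_) {
  ipd <- eyes$ipd
  box <- cfg$search.centroid_box_ipd * ipd
  pair <- sample_shape_pair(db, cls)
  lcent <- eyes$left_center + runif(2L, -box, box)
  size <- runif(1L, cfg$search.size_min_ipd, cfg$search.size_max_ipd) * ipd
  beta <- runif(1L)
  rx <- eyes$right_center[1L] + runif(1L, -box, box)
  glasses_hypothesis(cls, lcent, size, pair[[1L]], pair[[2L]], beta,
                     c(rx, lcent[2L]), gen_idx = gen_idx)
}

#' Monte Carlo hypothesis search for one shape class
#'
#' Draws `search.max_hypotheses` hypotheses uniformly from the domain,
#' keeps those passing [validate_hypothesis()] and scores each against the
#' distance field. Reconstruction, validation and scoring are batched.
#'
#' @param df distance field matrix.
#' @param eyes an `eye_region`.
#' @param roi search rectangle.
#' @param fifths a `face_fifths`.
#' @param db a `shape_database`.
#' @param cls shape class to search.
#' @param cfg a [lens_config()].
#' @return list of scored valid `glasses_hypothesis` objects (possibly
#'   empty).
#' @export
monte_carlo_search <- function(df, eyes, roi, fifths, db, cls,
                               cfg = lens_config()) {
  n <- cfg$search.max_hypotheses
  hyps <- lapply(seq_len(n), function(i)
    sample_hypothesis(cls, eyes, db, cfg, gen_idx = i))

  N <- hyps[[1L]]$n_points
  k <- hyps[[1L]]$k
  npts <- 64L
  cm <- t(vapply(hyps, hypothesis_norm_coeffs, complex(length(k))))
  sizes <- vapply(hyps, function(h) h$left$size, 0)
  lc <- t(vapply(hyps, function(h) h$left$centroid, numeric(2L)))
  rc <- t(vapply(hyps, function(h) h$right_centroid, numeric(2L)))

  scale <- sizes * N
  placedL <- cbind(N * complex(real = lc[, 1L], imaginary = lc[, 2L]),
                   cm * scale)
  flip_idx <- match(-k, k)
  cmf <- -Conj(cm[, flip_idx, drop = FALSE])
  placedR <- cbind(N * complex(real = rc[, 1L], imaginary = rc[, 2L]),
                   cmf * scale)
  kk <- c(0L, k)
  L <- reconstruct_xy(placedL, kk, N, npts)
  R <- reconstruct_xy(placedR, kk, N, npts)

  ok <- batch_validate(L, R, lc, rc, eyes, roi, fifths)
  keep <- which(ok)
  if (!length(keep)) return(list())

  sl <- cpp_score_polylines(L$x[keep, , drop = FALSE],
                            L$y[keep, , drop = FALSE], df)
  sr <- cpp_score_polylines(R$x[keep, , drop = FALSE],
                            R$y[keep, , drop = FALSE], df)
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    h <- hyps[[i]]
    h$score <- match_score(sl[j], sr[j])
    h$bbox <- c(min(L$x[i, ], R$x[i, ]), min(L$y[i, ], R$y[i, ]),
                max(L$x[i, ], R$x[i, ]), max(L$y[i, ], R$y[i, ]))
    out[[j]] <- h
  }
  out
}

# vectorized validation clauses over batch-reconstructed contours; mirrors
# validate_contour_pair()
batch_validate <- function(L, R, lc, rc, eyes, roi, fifths,
                           centroid_tol = 0.25) {
  ipd <- eyes$ipd
  bb <- function(M) list(min = apply(M, 1L, min), max = apply(M, 1L, max))
  lx <- bb(L$x); ly <- bb(L$y); rx <- bb(R$x); ry <- bb(R$y)

  encl <- cpp_point_in_polygons(L$x, L$y, eyes$left_center[1L],
                                eyes$left_center[2L]) &
    cpp_point_in_polygons(R$x, R$y, eyes$right_center[1L],
                          eyes$right_center[2L])
  cent <- sqrt((lc[, 1L] - eyes$left_center[1L])^2 +
               (lc[, 2L] - eyes$left_center[2L])^2) <= centroid_tol * ipd &
    sqrt((rc[, 1L] - eyes$right_center[1L])^2 +
         (rc[, 2L] - eyes$right_center[2L])^2) <= centroid_tol * ipd
  er_l <- eyes$left_rect; er_r <- eyes$right_rect
  size_ok <- (lx$max - lx$min > er_l[3L] - er_l[1L]) &
    (ly$max - ly$min > er_l[4L] - er_l[2L]) &
    (rx$max - rx$min > er_r[3L] - er_r[1L]) &
    (ry$max - ry$min > er_r[4L] - er_r[2L])
  br <- fifths$breaks
  fif <- lx$min >= br[1L] & lx$max <= br[4L] &
    rx$min >= br[3L] & rx$max <= br[6L]
  inroi <- lx$min >= roi[1L] & ly$min >= roi[2L] &
    lx$max <= roi[3L] & ly$max <= roi[4L] &
    rx$min >= roi[1L] & ry$min >= roi[2L] &
    rx$max <= roi[3L] & ry$max <= roi[4L]
  encl & cent & size_ok & fif & inroi
}

#' Overlap fraction of two axis-aligned rectangles
#'
#' Intersection area divided by the smaller rectangle's area — the cluster
#' merge criterion.
#'
#' @param r1,r2 rectangles `c(x0, y0, x1, y1)` with positive area.
#' @return overlap fraction in `[0, 1]`.
#' @export
rect_overlap_fraction <- function(r1, r2) {
  a1 <- (r1[3L] - r1[1L]) * (r1[4L] - r1[2L])
  a2 <- (r2[3L] - r2[1L]) * (r2[4L] - r2[2L])
  if (a1 <= 0 || a2 <= 0) stop("zero-area rectangle")
  iw <- min(r1[3L], r2[3L]) - max(r1[1L], r2[1L])
  ih <- min(r1[4L], r2[4L]) - max(r1[2L], r2[2L])
  max(0, iw) * max(0, ih) / min(a1, a2)
}

#' Agglomerative clustering of hypotheses by position and size
#'
#' Starting from singleton clusters, repeatedly merges the pair of
#' clusters with the largest mutual bounding-box overlap fraction while
#' that fraction is at least `alpha`; merging replaces both boxes by
#' their enclosing rectangle. A cluster's score is the mean combined
#' score of its members: a lone false positive with a lucky score sits in
#' a cluster dragged down by its poorly scoring neighbors, while the true
#' rim's cluster is uniformly good.
#'
#' @param hyps non-empty list of scored `glasses_hypothesis` objects.
#' @param alpha merge threshold in `(0, 1]` (default 0.90).
#' @return list of `hypothesis_cluster` objects (fields `members`,
#'   `bbox`, `cluster_score`), in order of first member appearance.
#' @export
cluster_hypotheses <- function(hyps, alpha = 0.90) {
  if (!length(hyps)) stop("cannot cluster an empty hypothesis list")
  bb <- t(vapply(hyps, function(h) {
    if (is.null(h$bbox)) hypothesis_bbox(h) else h$bbox
  }, numeric(4L)))
  ids <- cpp_cluster_bboxes(bb, alpha)
  lapply(unique(ids), function(ci) {
    idx <- which(ids == ci)
    members <- hyps[idx]
    bbox <- Reduce(rect_union, lapply(seq_along(idx),
                                      function(j) bb[idx[j], ]))
    scores <- vapply(members, function(h) h$score$combined, 0)
    structure(list(members = members, bbox = bbox,
                   cluster_score = mean(scores)),
              class = "hypothesis_cluster")
  })
}

#' @export
print.hypothesis_cluster <- function(x, ...) {
  cat(sprintf("<hypothesis_cluster: %d members, score %.3f px>\n",
              length(x$members), x$cluster_score))
  invisible(x)
}

#' Select the best hypothesis from the best cluster
#'
#' Picks the cluster with the minimal mean member score, then that
#' cluster's member with the minimal combined score. Ties break toward the
#' earliest cluster and the earliest generation index.
#'
#' @param clusters non-empty list of `hypothesis_cluster` objects.
#' @return the selected `glasses_hypothesis`.
#' @export
select_best <- function(clusters) {
  if (!length(clusters)) stop("no clusters to select from")
  cs <- vapply(clusters, `[[`, 0, "cluster_score")
  best <- clusters[[which.min(cs)]]
  ms <- vapply(best$members, function(h) h$score$combined, 0)
  cand <- which(ms == min(ms))
  if (length(cand) > 1L) {
    gen <- vapply(best$members[cand], `[[`, 0L, "gen_idx")
    cand <- cand[which.min(gen)]
  }
  best$members[[cand[1L]]]
}
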