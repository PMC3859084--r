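#' Gaussian proposal model for the random walk
#'
#' Per-dimension standard deviations of the proposal distribution centered
#' on the current solution: `sigma_position` (pixels) for either lens
#' centroid, `sigma_size` (pixels) for the lens size, `sigma_beta`
#' (unitless) for the morph factor.
#'
#' @param sigma_position,sigma_size,sigma_beta non-negative standard
#'   deviations.
#' @return object of class `proposal_model`.
#' @export
proposal_model <- function(sigma_position, sigma_size, sigma_beta) {
  if (sigma_position < 0 || sigma_size < 0 || sigma_beta < 0)
    stop("proposal sigmas must be non-negative")
  structure(list(sigma_position = sigma_position, sigma_size = sigma_size,
                 sigma_beta = sigma_beta), class = "proposal_model")
}

#' Random-walk refinement of a glasses hypothesis
#'
#' Hill-climbing around the Monte Carlo solution: at each iteration one
#' dimension is picked uniformly from {left centroid, right centroid,
#' size, beta} and perturbed by a Gaussian draw with the corresponding
#' sigma; the proposal is kept only if it stays valid and strictly lowers
#' the combined score. `beta` is clamped to `[0, 1]`; the reference shape
#' pair is never re-drawn. The returned score is therefore never worse
#' than the input's.
#'
#' @param x0 a scored, valid `glasses_hypothesis`.
#' @param df distance field matrix.
#' @param eyes an `eye_region`.
#' @param roi search rectangle.
#' @param fifths a `face_fifths`.
#' @param pm a `proposal_model`.
#' @param max_iterations number of proposals (default 30).
#' @return the refined `glasses_hypothesis` with attribute `trajectory`,
#'   the accepted combined score after each iteration.
#' @export
random_walk_refine <- function(x0, df, eyes, roi, fifths, pm,
                               max_iterations = 30L) {
  stopifnot(inherits(x0, "glasses_hypothesis"),
            inherits(pm, "proposal_model"))
  if (is.null(x0$score)) {
    ct <- hypothesis_contours(x0)
    x0$score <- hypothesis_score(ct$left, ct$right, df)
  }
  x <- x0
  traj <- numeric(max_iterations)
  for (it in seq_len(max_iterations)) {
    dim_pick <- sample.int(4L, 1L)
    xp <- x
    if (dim_pick == 1L) {
      xp$left$centroid <- x$left$centroid + rnorm(2L, 0, pm$sigma_position)
    } else if (dim_pick == 2L) {
      xp$right_centroid <- x$right_centroid + rnorm(2L, 0, pm$sigma_position)
    } else if (dim_pick == 3L) {
      xp$left$size <- max(x$left$size + rnorm(1L, 0, pm$sigma_size), 1e-6)
    } else {
      xp$left$beta <- min(max(x$left$beta + rnorm(1L, 0, pm$sigma_beta), 0), 1)
    }
    ct <- hypothesis_contours(xp)
    reason <- validate_contour_pair(ct$left, ct$right, xp$left$centroid,
                                    xp$right_centroid, eyes, roi, fifths)
    if (identical(reason, "ok")) {
      sc <- hypothesis_score(ct$left, ct$right, df)
      if (sc$combined < x$score$combined) {
        xp$score <- sc
        xp$bbox <- rect_union(contour_bbox(ct$left), contour_bbox(ct$right))
        x <- xp
      }
    }
    traj[it] <- x$score$combined
  }
  attr(x, "trajectory") <- traj
  x
}

#' End-to-end lens contour extraction
#'
#' Full pipeline: eye localization (or supplied centers), search ROI,
#' Canny edge map restricted to the ROI, Euclidean distance transform,
#' then per shape class: Monte Carlo sampling, hypothesis clustering,
#' best-cluster selection and random-walk refinement. The class solution
#' with the minimal combined score wins; extraction fails if no class
#' yields a valid hypothesis or the best score exceeds
#' `pipeline.reject_score` (too little edge support, e.g. rimless
#' frames).
#'
#' @param image grayscale intensity matrix (see [load_image()]).
#' @param db a `shape_database` (default [builtin_database()]).
#' @param cfg a [lens_config()]; `cfg$seed` seeds all randomness.
#' @param eyes optional `eye_region` to bypass detection.
#' @return object of class `extraction_result` with the winning
#'   hypothesis, its 64-point `left_contour` / `right_contour` in image
#'   coordinates, `score`, per-class best scores and the `eyes` used.
#' @export
extract_lenses <- function(image, db = builtin_database(),
                           cfg = lens_config(), eyes = NULL) {
  set.seed(cfg$seed)
  if (is.null(eyes))
    eyes <- detect_eyes(image, max_tilt_deg = cfg$eyes.max_tilt_deg)
  roi <- eyeglass_roi(eyes, cfg$roi.delta, dim = dim(image))
  edges <- edge_map(image, cfg$canny.low, cfg$canny.high,
                    sigma = cfg$canny.sigma, roi = roi)
  df <- distance_field(edges)
  fifths <- face_fifths(eyes)
  pm <- proposal_model(cfg$refine.sigma_pos_ipd * eyes$ipd,
                       cfg$refine.sigma_size_ipd * eyes$ipd,
                       cfg$refine.sigma_beta)

  class_scores <- setNames(rep(NA_real_, 3L), shape_classes())
  best <- NULL
  for (cls in shape_classes()) {
    hyps <- monte_carlo_search(df, eyes, roi, fifths, db, cls, cfg)
    if (!length(hyps)) next
    clusters <- cluster_hypotheses(hyps, cfg$search.alpha)
    x0 <- select_best(clusters)
    xr <- random_walk_refine(x0, df, eyes, roi, fifths, pm,
                             cfg$refine.max_iterations)
    class_scores[cls] <- xr$score$combined
    if (is.null(best) || xr$score$combined < best$score$combined) best <- xr
  }
  if (is.null(best))
    stop("extraction failed: no valid hypothesis in any shape class")
  if (best$score$combined > cfg$pipeline.reject_score)
    stop(sprintf(
      "extraction failed: best mean edge distance %.2f px exceeds %.2f",
      best$score$combined, cfg$pipeline.reject_score))
  ct <- hypothesis_contours(best)
  structure(list(left_contour = ct$left, right_contour = ct$right,
                 hypothesis = best, score = best$score,
                 class_scores = class_scores, eyes = eyes,
                 roi = roi),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf(
    "<extraction_result: class %s, score %.3f px, ipd %.1f px>\n",
    x$hypothesis$cls, x$score$combined, x$eyes$ipd))
  invisible(x)
}
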