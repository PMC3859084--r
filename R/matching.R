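#' Chamfer-style matching score of a rim contour
#'
#' The contour is rasterized as an 8-connected closed polyline and the
#' score is the mean of the distance field over the distinct rasterized
#' boundary pixels. The field is zero on edge pixels, so lower scores mean
#' better matches; a contour lying exactly on edges scores 0. Pixels
#' falling outside the field are clamped to the border and contribute the
#' border distance value.
#'
#' @param contour a contour matrix in pixel coordinates.
#' @param df distance field matrix from [distance_field()].
#' @return non-negative mean edge distance in pixels.
#' @export
rim_score <- function(contour, df) {
  contour <- as_contour(contour)
  s <- cpp_score_polylines(matrix(contour[, 1L], nrow = 1L),
                           matrix(contour[, 2L], nrow = 1L), df)
  if (is.na(s)) stop("contour produced no rasterized pixels")
  s
}

#' Match score of a left/right rim pair
#'
#' @param left,right contour matrices of the two rims.
#' @param df distance field matrix.
#' @return object of class `match_score` with fields `left`, `right` and
#'   `combined = (left + right) / 2`.
#' @export
hypothesis_score <- function(left, right, df) {
  l <- rim_score(left, df)
  r <- rim_score(right, df)
  match_score(l, r)
}

match_score <- function(left, right) {
  structure(list(left = left, right = right, combined = (left + right) / 2),
            class = "match_score")
}

#' @export
print.match_score <- function(x, ...) {
  cat(sprintf("<match_score: left %.3f, right %.3f, combined %.3f px>\n",
              x$left, x$right, x$combined))
  invisible(x)
}

#' Facial fifths from the eye geometry
#'
#' The neoclassical facial canon divides the face into five equal-width
#' vertical bands, the middle one spanning the intercanthal gap (between
#' the inner eye-rectangle edges). The remaining four bands extend
#' symmetrically outward with the same width. Lens placement is
#' constrained to bands 1-3 (left lens) and 3-5 (right lens).
#'
#' @param eyes an `eye_region`.
#' @return object of class `face_fifths` with `$breaks`, the six band
#'   boundaries (band i spans `[breaks[i], breaks[i+1])`).
#' @export
face_fifths <- function(eyes) {
  stopifnot(inherits(eyes, "eye_region"))
  inner_l <- eyes$left_rect[3L]   # inner edge of the left eye rect
  inner_r <- eyes$right_rect[1L]  # inner edge of the right eye rect
  if (inner_r <= inner_l)
    stop("eye rectangles overlap: no intercanthal gap")
  w <- inner_r - inner_l
  breaks <- inner_l + w * (-2:3)
  structure(list(breaks = breaks, width = w), class = "face_fifths")
}

#' Geometric validation of a glasses hypothesis
#'
#' A hypothesis is plausible only if all of the following hold:
#' \describe{
#'   \item{enclosure}{each eye center lies strictly inside its rim
#'     polygon;}
#'   \item{centroid}{each lens centroid is within `0.25 * ipd` of its eye
#'     center;}
#'   \item{size}{each lens bounding box is strictly larger than its eye
#'     rectangle in both dimensions;}
#'   \item{fifths}{the vertical sides of the left lens lie within facial
#'     bands 1-3 and those of the right lens within bands 3-5;}
#'   \item{roi}{both contours lie inside the search ROI.}
#' }
#'
#' @param hyp a `glasses_hypothesis` (see [sample_hypothesis()]).
#' @param eyes an `eye_region`.
#' @param roi search rectangle from [eyeglass_roi()].
#' @param fifths a `face_fifths`.
#' @param centroid_tol centroid distance tolerance as a fraction of IPD.
#' @return list with `ok` (logical) and `reason` (`"ok"` or the name of
#'   the first violated clause: `"enclosure"`, `"centroid"`, `"size"`,
#'   `"fifths"`, `"roi"`).
#' @export
validate_hypothesis <- function(hyp, eyes, roi, fifths,
                                centroid_tol = 0.25) {
  stopifnot(inherits(hyp, "glasses_hypothesis"))
  ct <- hypothesis_contours(hyp)
  reason <- validate_contour_pair(
    ct$left, ct$right, hyp$left$centroid, hyp$right_centroid,
    eyes, roi, fifths, centroid_tol)
  list(ok = identical(reason, "ok"), reason = reason)
}

# shared clause logic for the scalar and batch paths
validate_contour_pair <- function(left, right, lcent, rcent, eyes, roi,
                                  fifths, centroid_tol = 0.25) {
  ipd <- eyes$ipd
  lb <- contour_bbox(left); rb <- contour_bbox(right)

  if (!point_in_contour(left, eyes$left_center) ||
      !point_in_contour(right, eyes$right_center)) return("enclosure")
  if (sqrt(sum((lcent - eyes$left_center)^2)) > centroid_tol * ipd ||
      sqrt(sum((rcent - eyes$right_center)^2)) > centroid_tol * ipd)
    return("centroid")
  er_l <- eyes$left_rect; er_r <- eyes$right_rect
  if (!(lb[3L] - lb[1L] > er_l[3L] - er_l[1L] &&
        lb[4L] - lb[2L] > er_l[4L] - er_l[2L] &&
        rb[3L] - rb[1L] > er_r[3L] - er_r[1L] &&
        rb[4L] - rb[2L] > er_r[4L] - er_r[2L])) return("size")
  br <- fifths$breaks
  if (!(lb[1L] >= br[1L] && lb[3L] <= br[4L] &&
        rb[1L] >= br[3L] && rb[3L] <= br[6L])) return("fifths")
  if (!(lb[1L] >= roi[1L] && lb[2L] >= roi[2L] &&
        lb[3L] <= roi[3L] && lb[4L] <= roi[4L] &&
        rb[1L] >= roi[1L] && rb[2L] >= roi[2L] &&
        rb[3L] <= roi[3L] && rb[4L] <= roi[4L])) return("roi")
  "ok"
}

point_in_contour <- function(contour, p) {
  as.logical(cpp_point_in_polygons(matrix(contour[, 1L], nrow = 1L),
                                   matrix(contour[, 2L], nrow = 1L),
                                   p[1L], p[2L]))
}
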