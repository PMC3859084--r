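#' Boxing size of a lens
#'
#' Width and height of the lens bounding box (the optometric "boxing
#' system" dimensions).
#'
#' @param contour a lens contour matrix.
#' @return named numeric `c(width =, height =)` in pixels.
#' @export
boxing_size <- function(contour) {
  bb <- contour_bbox(contour)
  c(width = bb[3L] - bb[1L], height = bb[4L] - bb[2L])
}

#' Bridge width between the two rims
#'
#' Horizontal gap between the left rim's rightmost point and the right
#' rim's leftmost point (the boxing-system bridge convention).
#'
#' @param left,right the two lens contours.
#' @return gap in pixels (>= 0).
#' @export
bridge <- function(left, right) {
  lmax <- contour_bbox(left)[3L]
  rmin <- contour_bbox(right)[1L]
  if (rmin < lmax)
    stop("rims overlap horizontally: implausible extraction")
  rmin - lmax
}

#' Fitting height of a lens
#'
#' Vertical distance from the bottom of the lens (maximal y, image y
#' grows downward) to the pupil.
#'
#' @param contour lens contour matrix.
#' @param pupil length-2 `c(x, y)` pupil position.
#' @return distance in pixels (>= 0).
#' @export
fitting_height <- function(contour, pupil) {
  bb <- contour_bbox(contour)
  if (pupil[2L] < bb[2L] || pupil[2L] > bb[4L])
    stop("pupil lies outside the lens vertically: implausible geometry")
  bb[4L] - pupil[2L]
}

#' All frame measurements from an extraction result
#'
#' Computes bridge, per-lens boxing sizes and fitting heights from the
#' extracted contours. Pupil positions default to the detected eye
#' centers. If a pixel-to-millimeter scale is supplied, every value is
#' also reported in mm.
#'
#' @param result an `extraction_result` from [extract_lenses()].
#' @param scale_mm_per_px optional positive scale factor.
#' @param pupils optional list with `left` and `right` pupil coordinates
#'   overriding the eye centers.
#' @return object of class `glasses_measurements` (a named list; see
#'   fields in the examples).
#' @examples
#' \dontrun{
#' m <- measure_glasses(extract_lenses(img), scale_mm_per_px = 0.2)
#' m$bridge; m$boxing_left; m$fitting_right_mm
#' }
#' @export
measure_glasses <- function(result, scale_mm_per_px = NULL, pupils = NULL) {
  stopifnot(inherits(result, "extraction_result"))
  if (is.null(pupils))
    pupils <- list(left = result$eyes$left_center,
                   right = result$eyes$right_center)
  out <- list(
    bridge = bridge(result$left_contour, result$right_contour),
    boxing_left = boxing_size(result$left_contour),
    boxing_right = boxing_size(result$right_contour),
    fitting_left = fitting_height(result$left_contour, pupils$left),
    fitting_right = fitting_height(result$right_contour, pupils$right),
    scale_mm_per_px = scale_mm_per_px
  )
  if (!is.null(scale_mm_per_px)) {
    if (scale_mm_per_px <= 0) stop("scale_mm_per_px must be positive")
    out$bridge_mm <- out$bridge * scale_mm_per_px
    out$boxing_left_mm <- out$boxing_left * scale_mm_per_px
    out$boxing_right_mm <- out$boxing_right * scale_mm_per_px
    out$fitting_left_mm <- out$fitting_left * scale_mm_per_px
    out$fitting_right_mm <- out$fitting_right * scale_mm_per_px
  }
  structure(out, class = "glasses_measurements")
}

#' @export
print.glasses_measurements <- function(x, ...) {
  cat(sprintf(
    paste0("<glasses_measurements (px): bridge %.1f, boxing L %.1f x %.1f,",
           " R %.1f x %.1f, fitting L %.1f, R %.1f>\n"),
    x$bridge, x$boxing_left["width"], x$boxing_left["height"],
    x$boxing_right["width"], x$boxing_right["height"],
    x$fitting_left, x$fitting_right))
  invisible(x)
}
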