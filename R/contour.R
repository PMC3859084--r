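#' Closed contours
#'
#' A contour is an ordered sequence of 2D points in pixel coordinates,
#' implicitly closed (the last point connects back to the first). It is
#' stored as a plain numeric matrix with columns `x` and `y`.
#'
#' @param points numeric matrix with two columns (x, y) and at least three
#'   rows, all coordinates finite.
#' @return the validated contour matrix with columns named `x`, `y`.
#' @examples
#' sq <- as_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' contour_area(sq)
#' @export
as_contour <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("a contour must be a numeric matrix with two columns (x, y)")
  if (nrow(points) < 3L)
    stop("a contour needs at least 3 points")
  if (!all(is.finite(points)))
    stop("contour coordinates must be finite")
  colnames(points) <- c("x", "y")
  points
}

#' Contour centroid (mean of the vertex points)
#' @param contour a contour matrix, see [as_contour()].
#' @return length-2 numeric vector `c(x, y)`.
#' @export
contour_centroid <- function(contour) {
  contour <- as_contour(contour)
  c(mean(contour[, 1L]), mean(contour[, 2L]))
}

#' Unsigned polygon area of a closed contour (shoelace formula)
#' @inheritParams contour_centroid
#' @return non-negative area in square pixels.
#' @export
contour_area <- function(contour) {
  contour <- as_contour(contour)
  x <- contour[, 1L]; y <- contour[, 2L]
  j <- c(2:nrow(contour), 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Resample a closed contour to equally spaced points by arc length
#'
#' All database shapes are resampled to a common point count so their
#' descriptor sets share one frequency index set and can be morphed
#' coefficient-wise.
#'
#' @inheritParams contour_centroid
#' @param n number of output points (>= 3).
#' @return an `n` x 2 contour matrix.
#' @export
resample_contour <- function(contour, n = 64L) {
  contour <- as_contour(contour)
  if (n < 3L) stop("n must be at least 3")
  p <- rbind(contour, contour[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate contour with zero perimeter")
  s <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(p)] <- nrow(p) - 1L
  t0 <- (s - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  out <- p[idx, , drop = FALSE] * (1 - t0) + p[idx + 1L, , drop = FALSE] * t0
  as_contour(out)
}

#' Test whether a closed contour is simple (non-self-intersecting)
#'
#' Pairwise segment-intersection check; adjacent segments sharing a vertex
#' are exempt. Used to vet procedurally generated and morphed database
#' shapes, which must stay realistic rim outlines.
#'
#' @inheritParams contour_centroid
#' @return `TRUE` if no two non-adjacent edges intersect.
#' @export
is_simple_contour <- function(contour) {
  contour <- as_contour(contour)
  n <- nrow(contour)
  p <- contour
  q <- contour[c(2:n, 1L), , drop = FALSE]
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # segment n is adjacent to segment 1
    if (!length(js)) next
    o1 <- orient(p[i, 1], p[i, 2], q[i, 1], q[i, 2], p[js, 1], p[js, 2])
    o2 <- orient(p[i, 1], p[i, 2], q[i, 1], q[i, 2], q[js, 1], q[js, 2])
    o3 <- orient(p[js, 1], p[js, 2], q[js, 1], q[js, 2], p[i, 1], p[i, 2])
    o4 <- orient(p[js, 1], p[js, 2], q[js, 1], q[js, 2], q[i, 1], q[i, 2])
    if (any(o1 != o2 & o3 != o4)) return(FALSE)
  }
  TRUE
}

#' Canonicalize traversal of a closed contour
#'
#' Reorders the points to start at the rightmost vertex (ties broken by the
#' topmost) and to traverse clockwise on screen (positive shoelace sum in
#' the y-down image frame). Database entries are canonicalized before the
#' Fourier transform so that coefficient-wise morphing interpolates
#' corresponding boundary regions rather than arbitrary phase-shifted ones.
#'
#' @inheritParams contour_centroid
#' @return a contour matrix with the same point set, reordered.
#' @export
canonicalize_contour <- function(contour) {
  contour <- as_contour(contour)
  x <- contour[, 1L]; y <- contour[, 2L]
  j <- c(2:nrow(contour), 1L)
  if (sum(x * y[j] - x[j] * y) < 0)
    contour <- contour[rev(seq_len(nrow(contour))), , drop = FALSE]
  x <- contour[, 1L]; y <- contour[, 2L]
  cand <- which(x == max(x))
  start <- cand[which.min(y[cand])]
  idx <- c(start:nrow(contour), seq_len(start - 1L))
  as_contour(contour[idx, , drop = FALSE])
}

#' Bounding box of a contour
#' @inheritParams contour_centroid
#' @return rectangle `c(x0, y0, x1, y1)`.
#' @export
contour_bbox <- function(contour) {
  contour <- as_contour(contour)
  c(min(contour[, 1L]), min(contour[, 2L]),
    max(contour[, 1L]), max(contour[, 2L]))
}
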