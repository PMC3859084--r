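#' Load an image as a grayscale intensity matrix
#'
#' Reads PNG, JPEG or TIFF via EBImage, or plain/raw PGM (P2/P5) natively,
#' converting color inputs to luminance. The result is a numeric matrix
#' indexed `[y + 1, x + 1]` with intensities in `[0, 255]`.
#'
#' @param path image file path.
#' @return numeric intensity matrix (rows = image rows).
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such image file: %s", path))
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) == EBImage::Color)
    img <- EBImage::channel(img, "luminance")
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2L) m <- m[, , 1L]
  t(m) * 255  # EBImage stores [x, y]; transpose to [y, x]
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (expected P2 or P5)")
  vals <- integer(0)
  tokens <- character(0)
  while (length(tokens) < 3L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*$", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1L]])
    tokens <- tokens[nzchar(tokens)]
  }
  w <- as.integer(tokens[1L]); h <- as.integer(tokens[2L])
  maxval <- as.integer(tokens[3L])
  if (magic == "P5") {
    px <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    px <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(px, nrow = h, ncol = w, byrow = TRUE) * (255 / maxval)
}

#' Eye region: two eye centers with their rectangles
#'
#' @param left_center,right_center length-2 `c(x, y)` pixel coordinates;
#'   the left eye (subject's right on screen) must have the smaller x.
#' @param left_rect,right_rect rectangles `c(x0, y0, x1, y1)` containing
#'   their centers.
#' @return an object of class `eye_region` with the interpupillary
#'   distance in `$ipd`.
#' @export
eye_region <- function(left_center, right_center, left_rect, right_rect) {
  if (left_center[1L] >= right_center[1L])
    stop("left eye center must be left of the right eye center")
  inside <- function(p, r) p[1L] >= r[1L] && p[1L] <= r[3L] &&
    p[2L] >= r[2L] && p[2L] <= r[4L]
  if (!inside(left_center, left_rect) || !inside(right_center, right_rect))
    stop("eye centers must lie inside their rectangles")
  ipd <- sqrt(sum((right_center - left_center)^2))
  if (ipd <= 0) stop("degenerate interpupillary distance")
  structure(list(left_center = as.numeric(left_center),
                 right_center = as.numeric(right_center),
                 left_rect = as.numeric(left_rect),
                 right_rect = as.numeric(right_rect),
                 ipd = ipd),
            class = "eye_region")
}

#' @export
print.eye_region <- function(x, ...) {
  cat(sprintf("<eye_region: left (%.1f, %.1f), right (%.1f, %.1f), ipd %.1f>\n",
              x$left_center[1L], x$left_center[2L],
              x$right_center[1L], x$right_center[2L], x$ipd))
  invisible(x)
}

#' Interpupillary distance
#'
#' Euclidean distance between the two eye centers; the model's single
#' size-normalizing quantity.
#'
#' @param eyes an `eye_region`.
#' @return distance in pixels.
#' @export
interpupillary_distance <- function(eyes) {
  stopifnot(inherits(eyes, "eye_region"))
  sqrt(sum((eyes$right_center - eyes$left_center)^2))
}

#' Group candidate eye rectangles into an eye region
#'
#' Implements the candidate-grouping pipeline over any single-eye candidate
#' detector: (1) discard candidates without a left-right pair (another
#' candidate on the opposite side of the joint candidate centroid at
#' similar height: vertical offset within 25% of the candidate height or
#' within a 20 degree slope of the horizontal offset, so that head tilts
#' up to the tilt gate still pair);
#' (2) split survivors into left and right groups about their common
#' center; (3) merge overlapping zones on each side into their enclosing
#' rectangle; (4) take each eye center as the centroid of that side's
#' zones, with the eye area midway between the smallest zone and the mean
#' zone. A maximum inter-eye slope (head tilt) is enforced.
#'
#' @param image grayscale intensity matrix (see [load_image()]).
#' @param detector function taking the image and returning a data.frame of
#'   candidate rectangles with columns `x0, y0, x1, y1`; defaults to the
#'   dark-blob [template_eye_detector()] suited to synthetic scenes.
#' @param max_tilt_deg maximum inter-eye slope in degrees (default 10).
#' @return an `eye_region`.
#' @export
detect_eyes <- function(image, detector = template_eye_detector(),
                        max_tilt_deg = 10) {
  cand <- detector(image)
  if (is.null(cand) || nrow(cand) < 2L)
    stop("eye detection failed: fewer than two candidate regions")
  cx <- (cand$x0 + cand$x1) / 2
  cy <- (cand$y0 + cand$y1) / 2
  hh <- cand$y1 - cand$y0
  midx <- mean(cx)

  paired <- vapply(seq_len(nrow(cand)), function(i) {
    opposite <- if (cx[i] < midx) cx > midx else cx < midx
    tol <- pmax(0.25 * pmax(hh, hh[i]), tan(20 * pi / 180) * abs(cx - cx[i]))
    any(opposite & abs(cy - cy[i]) <= tol)
  }, logical(1L))
  cand <- cand[paired, , drop = FALSE]
  if (nrow(cand) < 2L)
    stop("eye detection failed: no left-right candidate pair")
  cx <- (cand$x0 + cand$x1) / 2
  cy <- (cand$y0 + cand$y1) / 2
  midx <- mean(cx)
  side <- ifelse(cx < midx, "left", "right")
  if (!all(c("left", "right") %in% side))
    stop("eye detection failed: no left-right candidate pair")

  merge_side <- function(z) {
    # merge overlapping zones into enclosing rectangles until stable
    repeat {
      merged <- FALSE
      i <- 1L
      while (i < nrow(z)) {
        j <- i + 1L
        while (j <= nrow(z)) {
          if (rect_intersects(unlist(z[i, ]), unlist(z[j, ]))) {
            z[i, ] <- c(min(z$x0[i], z$x0[j]), min(z$y0[i], z$y0[j]),
                        max(z$x1[i], z$x1[j]), max(z$y1[i], z$y1[j]))
            z <- z[-j, , drop = FALSE]
            merged <- TRUE
          } else j <- j + 1L
        }
        i <- i + 1L
      }
      if (!merged) break
    }
    z
  }

  side_result <- function(which_side) {
    z <- merge_side(cand[side == which_side, c("x0", "y0", "x1", "y1"),
                         drop = FALSE])
    center <- c(mean((z$x0 + z$x1) / 2), mean((z$y0 + z$y1) / 2))
    sizes <- cbind(z$x1 - z$x0, z$y1 - z$y0)
    dim_small <- sizes[which.min(sizes[, 1L] * sizes[, 2L]), ]
    dims <- (dim_small + colMeans(sizes)) / 2  # midpoint of smallest and mean
    rect <- c(center - dims / 2, center + dims / 2)
    list(center = center, rect = rect)
  }
  L <- side_result("left"); R <- side_result("right")

  tilt <- atan2(abs(R$center[2L] - L$center[2L]),
                abs(R$center[1L] - L$center[1L])) * 180 / pi
  if (tilt > max_tilt_deg)
    stop(sprintf("unusable pose: inter-eye slope %.1f deg exceeds %.1f deg",
                 tilt, max_tilt_deg))
  eye_region(L$center, R$center, L$rect, R$rect)
}

rect_intersects <- function(a, b) {
  a[1L] <= b[3L] && b[1L] <= a[3L] && a[2L] <= b[4L] && b[2L] <= a[4L]
}

#' Dark-blob candidate detector for synthetic scenes
#'
#' Thresholds dark pixels, labels connected components and keeps compact
#' blob-like ones (solid fill, near-isotropic, plausible area) as eye
#' candidates. Thin strokes such as rim lines and eyebrow arcs are
#' rejected by the fill-ratio test. Returns a detector function suitable
#' for [detect_eyes()].
#'
#' @param dark_quantile quantile locating the dark-feature intensity; the
#'   binarization threshold is the midpoint between it and the image
#'   median (the background level), robust to dark features covering only
#'   a small image fraction.
#' @param min_area minimum blob area in pixels.
#' @param min_fill minimum blob area / bounding-box area ratio.
#' @return function(image) -> data.frame(x0, y0, x1, y1).
#' @export
template_eye_detector <- function(dark_quantile = 0.002, min_area = 40,
                                  min_fill = 0.45) {
  function(image) {
    thr <- (stats::quantile(image, dark_quantile) +
              stats::median(image)) / 2
    mask <- EBImage::Image(t(image < thr) * 1)
    lab <- EBImage::bwlabel(mask)
    n <- max(lab)
    if (n < 1L) return(data.frame(x0 = numeric(0), y0 = numeric(0),
                                  x1 = numeric(0), y1 = numeric(0)))
    ld <- t(EBImage::imageData(lab))  # [y, x]
    pix <- which(ld > 0)
    lab_id <- ld[pix]
    yy <- (pix - 1L) %% nrow(ld)          # 0-based row
    xx <- (pix - 1L) %/% nrow(ld)         # 0-based col
    f <- factor(lab_id, levels = seq_len(n))
    x0 <- tapply(xx, f, min); x1 <- tapply(xx, f, max)
    y0 <- tapply(yy, f, min); y1 <- tapply(yy, f, max)
    area <- tabulate(lab_id, n)
    w <- x1 - x0 + 1; h <- y1 - y0 + 1
    keep <- area >= min_area & area / (w * h) >= min_fill &
      w / h >= 1 / 3 & w / h <= 3
    keep[is.na(keep)] <- FALSE
    data.frame(x0 = x0[keep], y0 = y0[keep], x1 = x1[keep], y1 = y1[keep])
  }
}

#' Build an eye region from supplied eye centers
#'
#' For images where eye localization is external (optometric devices often
#' supply pupil positions). Eye rectangles are nominal, sized relative to
#' the implied interpupillary distance.
#'
#' @param left,right length-2 `c(x, y)` centers, left having smaller x.
#' @param rect_w_ipd,rect_h_ipd nominal eye rectangle width and height as
#'   fractions of the IPD.
#' @return an `eye_region`.
#' @export
supplied_eyes <- function(left, right, rect_w_ipd = 0.25,
                          rect_h_ipd = 0.15) {
  ipd <- sqrt(sum((right - left)^2))
  half <- c(rect_w_ipd, rect_h_ipd) * ipd / 2
  eye_region(left, right,
             c(left - half, left + half),
             c(right - half, right + half))
}

#' Eyeglasses search region of interest
#'
#' Rectangle centered on the midpoint of the eye centers with width
#' `(1 + delta) * ipd` and height `delta * ipd`, clipped to the image.
#' `delta = 1.5` encloses even large frames while keeping the search
#' space bounded.
#'
#' @param eyes an `eye_region`.
#' @param delta expansion factor (> 0).
#' @param dim image dimensions `c(height, width)` for clipping, or `NULL`.
#' @return rectangle `c(x0, y0, x1, y1)` with attribute `delta`.
#' @export
eyeglass_roi <- function(eyes, delta = 1.5, dim = NULL) {
  stopifnot(inherits(eyes, "eye_region"))
  if (delta <= 0) stop("delta must be positive")
  ipd <- eyes$ipd
  mid <- (eyes$left_center + eyes$right_center) / 2
  half_w <- (1 + delta) * ipd / 2
  half_h <- delta * ipd / 2
  r <- c(mid[1L] - half_w, mid[2L] - half_h,
         mid[1L] + half_w, mid[2L] + half_h)
  if (!is.null(dim)) {
    r <- c(max(r[1L], 0), max(r[2L], 0),
           min(r[3L], dim[2L] - 1), min(r[4L], dim[1L] - 1))
    for (er in list(eyes$left_rect, eyes$right_rect))
      if (!(er[1L] >= r[1L] && er[2L] >= r[2L] &&
            er[3L] <= r[3L] && er[4L] <= r[4L]))
        stop("clipped ROI no longer contains both eye rectangles")
  }
  attr(r, "delta") <- delta
  r
}

#' Canny edge map
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression and
#' hysteresis thresholding. With `high = NA` the high threshold is derived
#' from an Otsu split of the gradient-magnitude histogram and
#' `low = high / 2`. When an ROI rectangle is given, edges are reported
#' only inside it.
#'
#' @param image grayscale intensity matrix.
#' @param low,high hysteresis thresholds on gradient magnitude
#'   (`0 <= low < high`), or `NA` to derive them.
#' @param sigma Gaussian blur standard deviation in pixels.
#' @param roi optional rectangle `c(x0, y0, x1, y1)` restricting the map.
#' @return binary integer matrix of the image size (1 = edge pixel).
#' @export
edge_map <- function(image, low = NA, high = NA, sigma = 1.4, roi = NULL) {
  if (!is.na(low) && !is.na(high) && !(low >= 0 && low < high))
    stop("invalid thresholds: need 0 <= low < high")
  if (is.na(high)) { high <- -1; low <- -1 }
  e <- cpp_canny(image, sigma, low, high)
  if (!is.null(roi)) {
    m <- matrix(0L, nrow(e), ncol(e))
    ys <- (max(0, floor(roi[2L])):min(nrow(e) - 1, ceiling(roi[4L]))) + 1L
    xs <- (max(0, floor(roi[1L])):min(ncol(e) - 1, ceiling(roi[3L]))) + 1L
    m[ys, xs] <- e[ys, xs]
    e <- m
  }
  e
}

#' Euclidean distance transform of an edge map
#'
#' Per-pixel Euclidean distance to the nearest edge pixel; zero exactly on
#' edges. The under-contour average of this field is the chamfer-style
#' matching score.
#'
#' @param edges binary edge matrix (1 = edge).
#' @return numeric matrix of distances (pixels).
#' @export
distance_field <- function(edges) {
  if (!any(edges > 0))
    stop("empty edge map: no edge pixels to measure distance to")
  d <- EBImage::distmap(EBImage::Image(t(1 - (edges > 0))),
                        metric = "euclidean")
  t(EBImage::imageData(d))
}
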