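#' Fourier descriptors of closed contours
#'
#' A closed contour with points \eqn{(x(i), y(i))} is treated as the
#' complex sequence \eqn{z(i) = x(i) + j y(i)} and described by its DFT
#' coefficients
#' \deqn{c(k) = \sum_{i=0}^{N-1} z(i) e^{-j 2\pi k i / N}.}
#' Low frequencies carry the coarse outline, high frequencies the detail.
#' `c(0)` is \eqn{N} times the centroid and is the only coefficient that
#' depends on position; the magnitude of `c(1)` scales linearly with the
#' shape, so dropping `c(0)` and dividing by `|c(1)|` yields descriptors
#' invariant to translation and scale. Rotation and start-point
#' normalization are deliberately not applied: rims are matched in image
#' orientation.
#'
#' A descriptor set keeps the retained coefficients, their signed frequency
#' indices, the source sampling count `N` and a `normalized` flag.
#'
#' @param coeffs complex vector of coefficients.
#' @param k integer vector of signed frequency indices, same length.
#' @param n_points the sampling count `N` of the source contour.
#' @param normalized logical; `TRUE` once `c(0)` is dropped and magnitudes
#'   are divided by `|c(1)|`.
#' @return an object of class `descriptor_set`.
#' @export
descriptor_set <- function(coeffs, k, n_points, normalized = FALSE) {
  coeffs <- as.complex(coeffs)
  k <- as.integer(k)
  if (length(coeffs) != length(k)) stop("coeffs and k must have equal length")
  if (anyDuplicated(k)) stop("duplicate frequency indices")
  if (length(coeffs) < 2L) stop("a descriptor set needs at least 2 coefficients")
  if (normalized && 0L %in% k)
    stop("a normalized descriptor set must not contain c(0)")
  structure(list(coeffs = coeffs, k = k, n_points = as.integer(n_points),
                 normalized = isTRUE(normalized)),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set: %d coefficients, N = %d, %s>\n",
              length(x$coeffs), x$n_points,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

# retained frequency order: lowest |k| first, +k before -k on ties
truncation_indices <- function(n_keep, n_points) {
  kmax <- floor(n_points / 2)
  ks <- c(0L, as.integer(rbind(seq_len(kmax), -seq_len(kmax))))
  ks <- ks[ks > -n_points / 2 | n_points %% 2L == 1L]  # avoid alias of Nyquist
  head(ks, n_keep)
}

fetch_coeff <- function(desc, k) {
  i <- match(k, desc$k)
  if (is.na(i)) complex(real = 0, imaginary = 0) else desc$coeffs[i]
}

#' Forward transform: contour to truncated Fourier descriptors
#'
#' Computes the unnormalized DFT of the complex boundary sequence and keeps
#' the `n_keep` coefficients of lowest absolute frequency (ties favoring
#' the positive index).
#'
#' @param contour a contour matrix, see [as_contour()].
#' @param n_keep number of coefficients to retain, `2 <= n_keep <=`
#'   number of points.
#' @return a raw (unnormalized) `descriptor_set`.
#' @examples
#' circ <- as_contour(cbind(5 * cos(2 * pi * (0:63) / 64),
#'                          5 * sin(2 * pi * (0:63) / 64)))
#' d <- contour_to_descriptors(circ, 14)
#' Mod(d$coeffs[d$k == 1])  # 5 * 64
#' @export
contour_to_descriptors <- function(contour, n_keep) {
  contour <- as_contour(contour)
  n <- nrow(contour)
  if (n_keep < 2L) stop("n_keep must be at least 2")
  if (n_keep > n) stop("n_keep cannot exceed the number of contour points")
  z <- complex(real = contour[, 1L], imaginary = contour[, 2L])
  ft <- fft(z)  # ft[k + 1] = c(k), k = 0..N-1; c(-k) = ft[N - k + 1]
  ks <- truncation_indices(n_keep, n)
  coeffs <- ft[ifelse(ks >= 0L, ks, n + ks) + 1L]
  descriptor_set(coeffs, ks, n)
}

#' Inverse transform: reconstruct a contour from descriptors
#'
#' Evaluates the truncated Fourier series (missing frequencies are zero)
#' at `n_points` equally spaced parameter values:
#' \deqn{z(i) = \frac{1}{N} \sum_k c(k) e^{+j 2\pi k i / n}.}
#' With the full coefficient set and `n_points = N` this is the exact
#' inverse DFT; with a truncated set it gives a smooth approximation of
#' the original outline. Keeping only `c(0)` and `c(1)` always yields a
#' circle.
#'
#' @param desc a `descriptor_set`.
#' @param n_points number of reconstruction points (>= 3).
#' @return a contour matrix.
#' @export
descriptors_to_contour <- function(desc, n_points = desc$n_points) {
  stopifnot(inherits(desc, "descriptor_set"))
  if (n_points < 3L) stop("n_points must be at least 3")
  xy <- reconstruct_xy(matrix(desc$coeffs, nrow = 1L), desc$k,
                       desc$n_points, n_points)
  as_contour(cbind(drop(xy$x), drop(xy$y)))
}

# Batch reconstruction: rows of `coeffs` are descriptor sets sharing the
# frequency index set `k` and the source count N; returns n x n_points
# matrices of x and y coordinates. Used by the Monte Carlo stage to
# reconstruct thousands of hypotheses in one matrix product.
reconstruct_xy <- function(coeffs, k, n_src, n_points) {
  i <- seq_len(n_points) - 1L
  basis <- exp(outer(k, i, function(kk, ii) 2i * pi * kk * ii / n_points))
  z <- (coeffs %*% basis) / n_src
  list(x = Re(z), y = Im(z))
}

#' Normalize descriptors to translation and scale invariance
#'
#' Removes `c(0)` (the position term) and divides every coefficient by the
#' scalar magnitude `|c(1)|` (the size term). Phases are untouched, so the
#' shape's orientation is preserved.
#'
#' @param desc a raw `descriptor_set` containing the `k = 1` coefficient.
#' @return a normalized `descriptor_set` with `|c(1)| = 1`.
#' @export
normalize_descriptors <- function(desc) {
  stopifnot(inherits(desc, "descriptor_set"))
  if (desc$normalized) return(desc)
  s <- Mod(fetch_coeff(desc, 1L))
  if (s < 1e-12)
    stop("degenerate shape: |c(1)| = 0, no first-harmonic extent")
  keep <- desc$k != 0L
  descriptor_set(desc$coeffs[keep] / s, desc$k[keep], desc$n_points,
                 normalized = TRUE)
}

#' Place a normalized shape at a position and size
#'
#' The inverse of normalization: multiplies all coefficients by `size`
#' (restoring `|c(1)| = size`) and inserts `c(0) = N * centroid` so the
#' reconstructed contour has the requested centroid. `size` is on the raw
#' `|c(1)|` scale; for an `N`-point circle of radius `r` pixels,
#' `|c(1)| = N * r`.
#'
#' @param norm a normalized `descriptor_set`.
#' @param centroid length-2 numeric `c(x, y)` in pixels.
#' @param size positive scalar, the target `|c(1)|`.
#' @return a raw `descriptor_set` including `c(0)`.
#' @export
place_descriptors <- function(norm, centroid, size) {
  stopifnot(inherits(norm, "descriptor_set"))
  if (!norm$normalized) stop("place_descriptors expects a normalized set")
  if (size <= 0) stop("size must be positive")
  c0 <- norm$n_points * complex(real = centroid[1L], imaginary = centroid[2L])
  descriptor_set(c(c0, norm$coeffs * size), c(0L, norm$k), norm$n_points)
}

#' Morph two shapes by linear combination of their descriptors
#'
#' \deqn{C_m = \beta C_{s1} + (1 - \beta) C_{s2}, \quad \beta \in [0, 1].}
#' Because a linear combination of Fourier series is itself a Fourier
#' series, the morph of two closed shapes is again a closed shape; for
#' same-class rim shapes the intermediates remain realistic rims.
#'
#' @param d1,d2 `descriptor_set`s with identical frequency index sets,
#'   sampling counts and normalization state.
#' @param beta morphing factor in `[0, 1]`; 1 returns `d1`, 0 returns `d2`.
#' @return a `descriptor_set`.
#' @export
morph_descriptors <- function(d1, d2, beta) {
  stopifnot(inherits(d1, "descriptor_set"), inherits(d2, "descriptor_set"))
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  if (!identical(d1$k, d2$k)) stop("mismatched frequency index sets")
  if (d1$normalized != d2$normalized) stop("mismatched normalization state")
  if (d1$n_points != d2$n_points) stop("mismatched sampling counts")
  descriptor_set(beta * d1$coeffs + (1 - beta) * d2$coeffs, d1$k,
                 d1$n_points, normalized = d1$normalized)
}

#' Mirror a shape about the vertical axis through its centroid
#'
#' The right rim of a pair of glasses is the horizontal mirror of the left
#' rim; flipping is done directly in descriptor space. Mirroring
#' \eqn{z \to 2 c_x - \overline{z}} maps \eqn{c(k) \to -\overline{c(-k)}}
#' for \eqn{k \ne 0} and leaves `c(0)` fixed, so the flipped set lives on
#' the negated frequency index set (identical for the symmetric index sets
#' used throughout the package). The reconstructed point set equals the
#' mirrored original point set; the traversal direction reverses.
#'
#' @param desc a `descriptor_set`.
#' @return the flipped `descriptor_set`.
#' @export
hflip_descriptors <- function(desc) {
  stopifnot(inherits(desc, "descriptor_set"))
  kf <- -desc$k
  cf <- -Conj(desc$coeffs)
  if (0L %in% desc$k) {
    i0 <- which(desc$k == 0L)
    cf[i0] <- desc$coeffs[i0]
    kf[i0] <- 0L
  }
  ord <- order(abs(kf), -sign(kf))
  descriptor_set(cf[ord], kf[ord], desc$n_points,
                 normalized = desc$normalized)
}

#' Serialize / deserialize a descriptor set
#'
#' The interchange format is a JSON object with fields `n_points`,
#' `indices`, `re`, `im` and `normalized`.
#'
#' @param desc a `descriptor_set`.
#' @return `descriptors_to_json` returns a JSON string;
#'   `descriptors_from_json` the parsed `descriptor_set`.
#' @export
descriptors_to_json <- function(desc) {
  stopifnot(inherits(desc, "descriptor_set"))
  jsonlite::toJSON(descriptors_to_list(desc), auto_unbox = TRUE, digits = NA)
}

descriptors_to_list <- function(desc) {
  list(n_points = desc$n_points, indices = desc$k,
       re = Re(desc$coeffs), im = Im(desc$coeffs),
       normalized = desc$normalized)
}

descriptors_from_list <- function(obj) {
  descriptor_set(complex(real = obj$re, imaginary = obj$im),
                 obj$indices, obj$n_points,
                 normalized = isTRUE(obj$normalized))
}

#' @param json a JSON string produced by `descriptors_to_json`.
#' @rdname descriptors_to_json
#' @export
descriptors_from_json <- function(json) {
  descriptors_from_list(jsonlite::fromJSON(json))
}
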