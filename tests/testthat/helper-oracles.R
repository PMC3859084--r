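# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as direct transcriptions of the definitions
# (O(N^2) sums, exhaustive pixel scans) and never call the code paths
# they check.

circle_contour <- function(r = 5, n = 64L, center = c(0, 0)) {
  t <- 2 * pi * (seq_len(n) - 1L) / n
  as_contour(cbind(center[1L] + r * cos(t), center[2L] + r * sin(t)))
}

# smooth rim-like test polygon (wide superellipse-ish outline)
rim_contour <- function(n = 64L, a = 40, b = 25, m = 3.5,
                        center = c(0, 0)) {
  t <- 2 * pi * (seq_len(n) - 1L) / n
  x <- a * sign(cos(t)) * abs(cos(t))^(2 / m)
  y <- b * sign(sin(t)) * abs(sin(t))^(2 / m)
  as_contour(cbind(center[1L] + x, center[2L] + y))
}

random_polygon <- function(n = 64L, scale = 20) {
  r <- scale * (1 + 0.3 * runif(n))
  t <- 2 * pi * (seq_len(n) - 1L) / n
  as_contour(cbind(r * cos(t), r * sin(t)))
}

# direct O(N^2) DFT of the complex boundary sequence
brute_dft <- function(contour, k) {
  z <- complex(real = contour[, 1L], imaginary = contour[, 2L])
  n <- length(z)
  i <- seq_len(n) - 1L
  vapply(k, function(kk) sum(z * exp(-2i * pi * kk * i / n)), complex(1L))
}

# direct O(N^2) inverse: evaluate the truncated series at n_points samples
brute_inverse <- function(coeffs, k, n_src, n_points) {
  i <- seq_len(n_points) - 1L
  z <- vapply(i, function(ii)
    sum(coeffs * exp(2i * pi * k * ii / n_points)) / n_src, complex(1L))
  cbind(Re(z), Im(z))
}

# exhaustive per-pixel distance to the nearest edge pixel
brute_distance_field <- function(edges) {
  ep <- which(edges > 0, arr.ind = TRUE)
  out <- matrix(0, nrow(edges), ncol(edges))
  for (y in seq_len(nrow(edges)))
    for (x in seq_len(ncol(edges)))
      out[y, x] <- sqrt(min((ep[, 1L] - y)^2 + (ep[, 2L] - x)^2))
  out
}

# textbook integer Bresenham over the closed polyline, distinct pixels
brute_raster <- function(contour) {
  n <- nrow(contour)
  px <- integer(0); py <- integer(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x0 <- round(contour[i, 1L]); y0 <- round(contour[i, 2L])
    x1 <- round(contour[j, 1L]); y1 <- round(contour[j, 2L])
    dx <- abs(x1 - x0); sx <- if (x0 < x1) 1L else -1L
    dy <- -abs(y1 - y0); sy <- if (y0 < y1) 1L else -1L
    err <- dx + dy; x <- x0; y <- y0
    repeat {
      px <- c(px, x); py <- c(py, y)
      if (x == x1 && y == y1) break
      e2 <- 2 * err
      if (e2 >= dy) { err <- err + dy; x <- x + sx }
      if (e2 <= dx) { err <- err + dx; y <- y + sy }
    }
    px <- px[-length(px)]; py <- py[-length(py)]
  }
  unique(cbind(px, py))
}

# mean distance-field value over the brute-rasterized boundary pixels
brute_rim_score <- function(contour, df) {
  pix <- brute_raster(contour)
  x <- pmin(pmax(pix[, 1L], 0L), ncol(df) - 1L)
  y <- pmin(pmax(pix[, 2L], 0L), nrow(df) - 1L)
  mean(df[cbind(y, x) + 1L][!duplicated(cbind(x, y))])
}

# maximal deviation of a reconstruction from the source points
max_deviation <- function(a, b) max(sqrt(rowSums((a - b)^2)))

# standard eye region used by matching/search fixtures: ipd 200 centered
# in an 800 x 600 frame
fixture_eyes <- function() {
  eye_region(c(300, 300), c(500, 300),
             c(286, 291, 314, 309), c(486, 291, 514, 309))
}

# count edge pixels lying within `tol` pixels of a contour polyline
edges_near_contour <- function(edges, contour, tol = 1) {
  ep <- which(edges > 0, arr.ind = TRUE)
  if (!nrow(ep)) return(0L)
  ex <- ep[, 2L] - 1; ey <- ep[, 1L] - 1
  n <- nrow(contour)
  j <- c(2:n, 1L)
  keep <- rep(FALSE, length(ex))
  for (i in seq_len(n)) {
    x0 <- contour[i, 1L]; y0 <- contour[i, 2L]
    dx <- contour[j[i], 1L] - x0; dy <- contour[j[i], 2L] - y0
    L2 <- dx^2 + dy^2
    t <- pmin(pmax(((ex - x0) * dx + (ey - y0) * dy) / L2, 0), 1)
    d2 <- (ex - (x0 + t * dx))^2 + (ey - (y0 + t * dy))^2
    keep <- keep | d2 <= tol^2
  }
  sum(keep)
}

# hypothesis built from the first two database entries of a class
make_hyp <- function(db, cls, centroid, size, right_centroid = NULL,
                     beta = 0.5, gen_idx = NA_integer_) {
  idx <- which(vapply(db$entries, `[[`, "", "cls") == cls)
  if (is.null(right_centroid))
    right_centroid <- c(800 - centroid[1L], centroid[2L])
  glasses_hypothesis(cls, centroid, size, db$entries[[idx[1L]]],
                     db$entries[[idx[2L]]], beta, right_centroid,
                     gen_idx = gen_idx)
}
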