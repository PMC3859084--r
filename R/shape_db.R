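#' Eyeglasses rim shape classes
#'
#' Rim shapes are grouped into three classes by shape similarity:
#' symmetrical rectangular rims, symmetrical elliptic rims and asymmetric
#' rims (e.g. aviator-like, fuller at the bottom). Morphing is only
#' performed within a class so that intermediate shapes remain realistic
#' rims.
#'
#' @return character vector of the three class labels.
#' @export
shape_classes <- function() {
  c("rectangular_symmetric", "elliptic_symmetric", "asymmetric")
}

#' Construct a shape database
#'
#' A shape database holds normalized left-rim descriptor sets tagged with
#' an id and a rim class. All entries must be normalized and share one
#' frequency index set and sampling count, so any same-class pair can be
#' morphed coefficient-wise.
#'
#' @param entries list of `list(id =, cls =, desc =)` with `desc` a
#'   normalized `descriptor_set`.
#' @return an object of class `shape_database`.
#' @export
shape_database <- function(entries) {
  if (!length(entries)) stop("a shape database needs at least one entry")
  ref <- entries[[1L]]$desc
  for (e in entries) {
    if (!is.character(e$id) || !nzchar(e$id))
      stop("every database entry needs a non-empty id")
    if (!e$cls %in% shape_classes())
      stop(sprintf("entry '%s': unknown shape class '%s'", e$id, e$cls))
    d <- e$desc
    if (!inherits(d, "descriptor_set") || !d$normalized)
      stop(sprintf("entry '%s': descriptors are not normalized", e$id))
    if (abs(Mod(fetch_coeff(d, 1L)) - 1) > 1e-6)
      stop(sprintf("entry '%s': |c(1)| != 1 in a normalized set", e$id))
    if (!identical(d$k, ref$k) || d$n_points != ref$n_points)
      stop(sprintf("entry '%s': inconsistent frequency index set", e$id))
  }
  structure(list(entries = entries), class = "shape_database")
}

#' @export
print.shape_database <- function(x, ...) {
  cls <- vapply(x$entries, `[[`, "", "cls")
  cat(sprintf("<shape_database: %d entries (%s)>\n", length(x$entries),
              paste(sprintf("%s: %d", names(table(cls)), table(cls)),
                    collapse = ", ")))
  invisible(x)
}

db_entry_ids <- function(db) vapply(db$entries, `[[`, "", "id")
db_entry_classes <- function(db) vapply(db$entries, `[[`, "", "cls")

db_find <- function(db, id) {
  i <- match(id, db_entry_ids(db))
  if (is.na(i)) stop(sprintf("no database entry with id '%s'", id))
  db$entries[[i]]
}

# superellipse |x/a|^m + |y/b|^m = 1, optionally with a vertical fullness
# term (bottom-heavier for skew > 0, image y grows downward) and a shear of
# the lower part; returns a 64-point canonical contour
superellipse_contour <- function(a, b, m, skew = 0, shear = 0,
                                 n_dense = 512L, n_out = 64L) {
  t <- seq(0, 2 * pi, length.out = n_dense + 1L)[seq_len(n_dense)]
  x <- a * sign(cos(t)) * abs(cos(t))^(2 / m)
  y <- b * sign(sin(t)) * abs(sin(t))^(2 / m)
  if (skew != 0) y <- y * (1 + skew * y / b)
  if (shear != 0) x <- x + shear * y
  canonicalize_contour(resample_contour(cbind(x, y), n_out))
}

# normalized descriptor set of a contour: 15 lowest-|k| raw coefficients
# {0, +-1..+-7}, then c(0) dropped and magnitudes divided by |c(1)|,
# leaving the 14 shape-carrying coefficients {+-1..+-7}
normalized_shape <- function(contour, n_desc = 14L) {
  normalize_descriptors(contour_to_descriptors(contour, n_desc + 1L))
}

#' Built-in shape database
#'
#' Procedurally populated database of left-rim shapes: superellipses with
#' high exponent and wide aspect for the rectangular class, near-elliptic
#' exponents for the elliptic class, and bottom-heavy sheared blends for
#' the asymmetric class, each family swept over a deterministic parameter
#' grid. Every entry is guaranteed to reconstruct as a simple closed curve.
#'
#' @param n_desc number of normalized descriptors per entry.
#' @return a `shape_database` with at least 40 entries across the three
#'   classes.
#' @examples
#' db <- builtin_database()
#' db
#' @export
builtin_database <- function(n_desc = 14L) {
  entries <- list()
  add <- function(id, cls, contour)
    entries[[length(entries) + 1L]] <<-
      list(id = id, cls = cls, desc = normalized_shape(contour, n_desc))

  # rectangular: exponents 3.5..7, aspects 1.25..1.7
  ms <- seq(3.5, 7, length.out = 14L)
  as <- rep(c(1.25, 1.4, 1.55, 1.7), length.out = 14L)
  for (i in seq_len(14L))
    add(sprintf("rect_%02d", i), "rectangular_symmetric",
        superellipse_contour(as[i], 1, ms[i]))

  # elliptic: exponents 1.7..2.4, aspects 1.05..1.5
  ms <- seq(1.7, 2.4, length.out = 14L)
  as <- rep(c(1.05, 1.2, 1.35, 1.5), length.out = 14L)
  for (i in seq_len(14L))
    add(sprintf("ellip_%02d", i), "elliptic_symmetric",
        superellipse_contour(as[i], 1, ms[i]))

  # asymmetric: moderate exponents with bottom fullness and shear
  ms <- seq(2.0, 3.2, length.out = 14L)
  sk <- rep(c(0.18, 0.25, 0.32), length.out = 14L)
  sh <- rep(c(-0.12, 0, 0.12, 0.2), length.out = 14L)
  as <- rep(c(1.2, 1.35, 1.5), length.out = 14L)
  for (i in seq_len(14L))
    add(sprintf("asym_%02d", i), "asymmetric",
        superellipse_contour(as[i], 1, ms[i], skew = sk[i], shear = sh[i]))

  shape_database(entries)
}

#' Read / write a shape database file
#'
#' The file format is a JSON array of entries, each the descriptor
#' serialization object (`n_points`, `indices`, `re`, `im`, `normalized`)
#' plus `id` and `class` fields. Loading validates every entry (normalized
#' flag, `|c(1)| = 1`, consistent index sets, known class).
#'
#' @param path file path.
#' @return `load_database` returns a `shape_database`.
#' @export
load_database <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such database file: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  entries <- lapply(raw, function(e) {
    if (!isTRUE(e$normalized))
      stop(sprintf("entry '%s': database entries must be normalized",
                   as.character(e$id)))
    list(id = e$id, cls = e$class, desc = descriptors_from_list(e))
  })
  shape_database(entries)
}

#' @param db a `shape_database`.
#' @rdname load_database
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "shape_database"))
  out <- lapply(db$entries, function(e)
    c(list(id = e$id, class = e$cls), descriptors_to_list(e$desc)))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Draw a random same-class shape pair from the database
#'
#' Both reference shapes of a rim hypothesis are drawn uniformly with
#' replacement from the requested class (the pair may repeat an entry, in
#' which case the morph degenerates to that shape). Uses the R global RNG;
#' seed with [set.seed()] for reproducibility.
#'
#' @param db a `shape_database`.
#' @param cls one of [shape_classes()].
#' @return list of the two entries (`id`, `cls`, `desc` each).
#' @export
sample_shape_pair <- function(db, cls) {
  stopifnot(inherits(db, "shape_database"))
  if (!cls %in% shape_classes()) stop(sprintf("unknown shape class '%s'", cls))
  idx <- which(db_entry_classes(db) == cls)
  if (!length(idx)) stop(sprintf("shape class '%s' has no entries", cls))
  pick <- idx[sample.int(length(idx), 2L, replace = TRUE)]
  list(db$entries[[pick[1L]]], db$entries[[pick[2L]]])
}

#' Verbatim published sample descriptors
#'
#' Loads the three published per-class sample descriptor lists shipped
#' with the package (see `inst/extdata/published_rim_samples.json`). The
#' frequency index mapping is a documented assumption, so these serve as
#' serialization and flip-test fixtures only and are not part of the
#' morphable [builtin_database()].
#'
#' @return named list of raw `descriptor_set`s with attributes `class`
#'   per entry.
#' @export
published_rim_fixtures <- function() {
  path <- system.file("extdata", "published_rim_samples.json",
                      package = "lenstrace")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(raw$entries, function(e) {
    d <- descriptors_from_list(e)
    attr(d, "rim_class") <- e$class
    d
  })
  names(out) <- vapply(raw$entries, `[[`, "", "id")
  out
}
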