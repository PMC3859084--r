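#' Pipeline configuration
#'
#' All tunable parameters of the extraction pipeline with their defaults.
#' Unknown keys are rejected. Values with a documented published setting:
#' `roi.delta = 1.5` (ROI expansion relative to the interpupillary
#' distance), `descriptors = 14` (normalized coefficients per shape),
#' `search.alpha = 0.90` (minimum bounding-box overlap fraction for
#' cluster merging), `refine.max_iterations = 30` as the published
#' heuristic (see below for this package's default), and `gamma = 0.95`
#' (overlap fraction at which a detection counts as a true positive).
#'
#' @param ... named overrides of the defaults listed below.
#' @return a named list of class `lens_config`.
#' @section Keys:
#' \describe{
#'   \item{canny.sigma, canny.low, canny.high}{Gaussian blur sigma and the
#'     hysteresis thresholds; `canny.high = NA` derives the high threshold
#'     from an Otsu split of the gradient-magnitude histogram, with
#'     `low = high / 2`.}
#'   \item{roi.delta}{ROI expansion factor (default 1.5).}
#'   \item{eyes.mode}{one of `"template"`, `"supplied"`, `"detector"`.}
#'   \item{eyes.max_tilt_deg}{maximum inter-eye slope (default 10).}
#'   \item{descriptors}{normalized descriptor count per shape (default 14).}
#'   \item{search.max_hypotheses}{Monte Carlo draws per class (default
#'     4000).}
#'   \item{search.alpha}{cluster merge overlap threshold (default 0.90).}
#'   \item{search.centroid_box_ipd}{half-width of the centroid sampling box
#'     around each eye center, as a fraction of IPD (default 0.25).}
#'   \item{search.size_min_ipd, search.size_max_ipd}{lens size bounds as
#'     fractions of IPD (defaults 0.35, 0.70).}
#'   \item{refine.max_iterations}{random-walk iterations (default 150;
#'     the published heuristic of 30 suffices only when the sampling stage
#'     already lands very close to the optimum).}
#'   \item{refine.sigma_pos_ipd, refine.sigma_size_ipd, refine.sigma_beta}{
#'     Gaussian proposal standard deviations: position and size as
#'     fractions of IPD (default 0.02 each), morph factor (default 0.05).}
#'   \item{pipeline.reject_score}{mean edge distance (pixels) above which
#'     extraction is declared failed (default 5).}
#'   \item{gamma}{true-positive overlap criterion for evaluation
#'     (default 0.95).}
#'   \item{seed}{integer seed for all randomness (default 1).}
#' }
#' @examples
#' cfg <- lens_config(search.max_hypotheses = 500)
#' cfg$roi.delta
#' @export
lens_config <- function(...) {
  defaults <- list(
    canny.sigma = 1.4,
    canny.low = NA_real_,
    canny.high = NA_real_,
    roi.delta = 1.5,
    eyes.mode = "template",
    eyes.max_tilt_deg = 10,
    descriptors = 14L,
    search.max_hypotheses = 4000L,
    search.alpha = 0.90,
    search.centroid_box_ipd = 0.25,
    search.size_min_ipd = 0.35,
    search.size_max_ipd = 0.70,
    refine.max_iterations = 150L,
    refine.sigma_pos_ipd = 0.02,
    refine.sigma_size_ipd = 0.02,
    refine.sigma_beta = 0.05,
    pipeline.reject_score = 5,
    gamma = 0.95,
    seed = 1L
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, over)
  validate_config(cfg)
  structure(cfg, class = "lens_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(sprintf("invalid config: %s", msg))
  chk(cfg$roi.delta > 0, "roi.delta must be positive")
  chk(cfg$eyes.mode %in% c("template", "supplied", "detector"),
      "eyes.mode must be one of template, supplied, detector")
  chk(cfg$eyes.max_tilt_deg > 0 && cfg$eyes.max_tilt_deg <= 45,
      "eyes.max_tilt_deg out of range")
  chk(cfg$descriptors >= 4 && cfg$descriptors %% 2L == 0L,
      "descriptors must be an even count >= 4")
  chk(cfg$search.max_hypotheses >= 1, "search.max_hypotheses must be >= 1")
  chk(cfg$search.alpha > 0 && cfg$search.alpha <= 1,
      "search.alpha must be in (0, 1]")
  chk(cfg$search.centroid_box_ipd > 0, "search.centroid_box_ipd must be > 0")
  chk(cfg$search.size_min_ipd > 0 &&
        cfg$search.size_min_ipd < cfg$search.size_max_ipd,
      "lens size bounds must satisfy 0 < min < max")
  chk(cfg$refine.max_iterations >= 0, "refine.max_iterations must be >= 0")
  chk(cfg$refine.sigma_pos_ipd >= 0 && cfg$refine.sigma_size_ipd >= 0 &&
        cfg$refine.sigma_beta >= 0, "proposal sigmas must be non-negative")
  chk(cfg$gamma > 0 && cfg$gamma <= 1, "gamma must be in (0, 1]")
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are config keys.
#' @return a `lens_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  obj <- yaml::read_yaml(path)
  if (is.null(obj)) obj <- list()
  do.call(lens_config, obj)
}
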