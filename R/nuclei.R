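# Nuclei segmentation and dead/mitotic-cell filtering under the two screen
# parameter profiles.

#' Segmentation parameter profile
#'
#' The `primary` profile smooths with FWHM 6 px, keeps objects with
#' equivalent diameter >= 35 px, and removes dead/mitotic nuclei on
#' too-high intensity SD, too-high upper-quartile intensity and too-small
#' area. The `secondary` profile gates diameter to 23-43 px and removes on
#' too-high intensity SD, too-low eccentricity (very round cells) and
#' too-high solidity.
#'
#' Numeric filter thresholds are not part of the published pipeline; the
#' defaults here were calibrated once on the synthetic null scene
#' (1st/99th percentiles of normal-cell features, see the methods vignette
#' and [calibrate_viability_thresholds()]) and are fully overridable.
#'
#' @param name `"primary"` or `"secondary"`.
#' @param smooth_fwhm Gaussian FWHM in pixels.
#' @param diameter_range Length-2 numeric `(min, max)`; `max` may be `Inf`.
#' @param filter_rules Named character vector: feature -> direction
#'   (`"high"` removes objects above the threshold, `"low"` below).
#' @param thresholds Named numeric vector with one value per rule.
#' @return A `segmentation_profile` list.
#' @export
segmentation_profile <- function(name = c("primary", "secondary"),
                                 smooth_fwhm = NULL, diameter_range = NULL,
                                 filter_rules = NULL, thresholds = NULL) {
  name <- match.arg(name)
  defaults <- if (name == "primary") {
    list(smooth_fwhm = 6, diameter_range = c(35, Inf),
         filter_rules = c(sd_intensity = "high", q75_intensity = "high",
                          area = "low"),
         thresholds = c(sd_intensity = 0.071, q75_intensity = 0.344,
                        area = 970))
  } else {
    list(smooth_fwhm = 6, diameter_range = c(23, 43),
         filter_rules = c(sd_intensity = "high", eccentricity = "low",
                          solidity = "high"),
         thresholds = c(sd_intensity = 0.074, eccentricity = 0.357,
                        solidity = 1.0))
  }
  p <- list(
    name = name,
    smooth_fwhm = smooth_fwhm %||% defaults$smooth_fwhm,
    diameter_range = diameter_range %||% defaults$diameter_range,
    filter_rules = filter_rules %||% defaults$filter_rules,
    thresholds = thresholds %||% defaults$thresholds
  )
  stopifnot(p$diameter_range[1] > 0,
            length(p$diameter_range) == 2,
            p$diameter_range[2] > p$diameter_range[1],
            all(p$filter_rules %in% c("high", "low")))
  class(p) <- "segmentation_profile"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment nuclei in a preprocessed frame
#'
#' Gaussian smoothing, global Otsu threshold, 8-connected labeling, then an
#' equivalent-diameter gate (`2 * sqrt(area / pi)`). Features are measured
#' on the input (unsmoothed) frame.
#'
#' @param frame Preprocessed numeric matrix.
#' @param profile A [segmentation_profile()].
#' @return A data.frame of nucleus objects (see [region_props()]); empty for
#'   a constant frame.
#' @export
segment_nuclei <- function(frame, profile = segmentation_profile("primary")) {
  if (max(frame) <= min(frame)) return(empty_props())
  sm <- smooth_gaussian(frame, fwhm = profile$smooth_fwhm)
  thr <- otsu_threshold(sm)
  labels <- label_components(sm > thr)
  # gate on equivalent diameter before the (costly) shape features
  area <- tabulate(labels[labels > 0])
  eqd <- 2 * sqrt(area / pi)
  bad <- which(eqd < profile$diameter_range[1] | eqd > profile$diameter_range[2])
  if (length(bad)) labels[labels %in% bad] <- 0L
  props <- region_props(labels, frame, shape = TRUE)
  attr(props, "labels") <- labels
  props
}

#' Filter dead and mitotic nuclei
#'
#' An object is removed iff it violates any rule: feature strictly greater
#' than the threshold for `"high"` rules, strictly smaller for `"low"`
#' rules. Objects exactly at a threshold are kept.
#'
#' @param objects Nucleus table from [segment_nuclei()].
#' @param profile A [segmentation_profile()] providing the rules.
#' @param thresholds Named numeric vector overriding the profile thresholds.
#' @return List with `kept` and `removed` (disjoint, exhaustive partition).
#' @export
filter_viable <- function(objects, profile, thresholds = NULL) {
  thresholds <- thresholds %||% profile$thresholds
  rules <- profile$filter_rules
  missing <- setdiff(names(rules), names(thresholds))
  if (length(missing))
    stop("missing threshold(s) for rule feature(s): ",
         paste(missing, collapse = ", "))
  if (nrow(objects) == 0) return(list(kept = objects, removed = objects))
  bad <- rep(FALSE, nrow(objects))
  for (feat in names(rules)) {
    v <- objects[[feat]]
    if (is.null(v)) stop("objects lack feature: ", feat)
    bad <- bad | if (rules[[feat]] == "high") v > thresholds[[feat]]
                 else v < thresholds[[feat]]
  }
  list(kept = objects[!bad, , drop = FALSE],
       removed = objects[bad, , drop = FALSE])
}

#' Calibrate viability-filter thresholds from a null population
#'
#' Sets each rule's threshold at the 1st (for `"low"` rules) or 99th (for
#' `"high"` rules) percentile of the given normal-cell feature values, the
#' convention used to derive the packaged profile defaults.
#'
#' @param objects Feature table of known-normal nuclei.
#' @param profile A [segmentation_profile()].
#' @return Named numeric vector of thresholds.
#' @export
calibrate_viability_thresholds <- function(objects, profile) {
  rules <- profile$filter_rules
  vapply(names(rules), function(feat) {
    p <- if (rules[[feat]] == "high") 0.99 else 0.01
    unname(quantile(objects[[feat]], p))
  }, 0)
}
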