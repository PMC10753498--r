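# Colocalization quantifications: Manders M1, object-based colocalization,
# proximity-ligation radius positivity, and intensity line profiles.

#' Manders M1 coefficient
#'
#' Fraction of channel-1 intensity residing in pixels where channel 2
#' exceeds `ch2_threshold` (0 by default, the definition used for the
#' histone-mark overlap analysis), optionally within a region of interest.
#'
#' @param ch1,ch2 Numeric matrices of equal shape.
#' @param roi Optional logical mask of the same shape.
#' @param ch2_threshold Channel-2 gate.
#' @return M1 in `[0, 1]`; `NA` with a warning when channel 1 has zero total
#'   intensity in the ROI.
#' @export
manders_m1 <- function(ch1, ch2, roi = NULL, ch2_threshold = 0) {
  if (!all(dim(ch1) == dim(ch2))) stop("channel shapes differ")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(ch1), ncol(ch1))
  total <- sum(ch1[roi])
  if (total == 0) {
    warning("channel 1 has zero total intensity; M1 undefined")
    return(NA_real_)
  }
  sum(ch1[roi & ch2 > ch2_threshold]) / total
}

#' Object-based colocalization fraction
#'
#' With the default `"centroid_in_mask"` rule, an object of A colocalizes
#' iff the pixel under its centroid lies inside any object of B; the
#' `"centroid_distance"` alternative requires a B centroid within
#' `max_distance` pixels.
#'
#' @param labelsA,labelsB Integer label matrices on the same frame.
#' @param rule Colocalization rule.
#' @param max_distance Centroid distance gate for the distance rule.
#' @return List `fraction_ab, fraction_ba, nA, nA_coloc, nB, nB_coloc`;
#'   fractions are `NA` with a warning when the corresponding set is empty.
#' @export
object_coloc_fraction <- function(labelsA, labelsB,
                                  rule = c("centroid_in_mask", "centroid_distance"),
                                  max_distance = 3) {
  rule <- match.arg(rule)
  stopifnot(all(dim(labelsA) == dim(labelsB)))
  centroids <- function(lab) {
    idx <- which(lab > 0)
    if (!length(idx)) return(NULL)
    nr <- nrow(lab)
    d <- data.frame(label = lab[idx], r = (idx - 1) %% nr + 1,
                    c = (idx - 1) %/% nr + 1)
    cbind(r = tapply(d$r, d$label, mean), c = tapply(d$c, d$label, mean))
  }
  ca <- centroids(labelsA); cb <- centroids(labelsB)
  hit <- function(cen, other_lab, other_cen) {
    if (is.null(cen)) return(NULL)
    if (rule == "centroid_in_mask") {
      ri <- pmin(pmax(round(cen[, "r"]), 1), nrow(other_lab))
      ci <- pmin(pmax(round(cen[, "c"]), 1), ncol(other_lab))
      other_lab[cbind(ri, ci)] > 0
    } else {
      if (is.null(other_cen)) return(rep(FALSE, nrow(cen)))
      apply(cen, 1, function(p)
        min(sqrt((other_cen[, "r"] - p["r"])^2 +
                 (other_cen[, "c"] - p["c"])^2)) <= max_distance)
    }
  }
  ha <- hit(ca, labelsB, cb); hb <- hit(cb, labelsA, ca)
  frac <- function(h, what) {
    if (is.null(h)) {
      warning("no ", what, " objects; fraction undefined")
      return(NA_real_)
    }
    mean(h)
  }
  list(fraction_ab = frac(ha, "A"), fraction_ba = frac(hb, "B"),
       nA = if (is.null(ca)) 0L else nrow(ca),
       nA_coloc = if (is.null(ha)) 0L else sum(ha),
       nB = if (is.null(cb)) 0L else nrow(cb),
       nB_coloc = if (is.null(hb)) 0L else sum(hb))
}

#' Fraction of bodies with a proximity-ligation signal within a radius
#'
#' A body is positive iff the nearest punctum lies within `radius_um`
#' micrometers (1.5 by default) of its center.
#'
#' @param bodies,puncta Two-column matrices of (row, col) pixel centroids.
#' @param radius_um Positivity radius in micrometers.
#' @param pixel_size Pixel size in micrometers per pixel (> 0).
#' @return Positive fraction in `[0, 1]`; `NA` with a warning if there are
#'   no bodies; 0 if there are bodies but no puncta.
#' @export
pla_positive_fraction <- function(bodies, puncta, radius_um = 1.5, pixel_size) {
  stopifnot(pixel_size > 0)
  bodies <- rbind(bodies); puncta <- rbind(puncta)
  if (is.null(bodies) || nrow(bodies) == 0) {
    warning("no bodies; PLA-positive fraction undefined")
    return(NA_real_)
  }
  if (is.null(puncta) || nrow(puncta) == 0) return(0)
  r_px <- radius_um / pixel_size
  pos <- vapply(seq_len(nrow(bodies)), function(i) {
    min(sqrt((puncta[, 1] - bodies[i, 1])^2 +
             (puncta[, 2] - bodies[i, 2])^2)) <= r_px
  }, TRUE)
  mean(pos)
}

#' Intensity profile along a line, with optional normalization
#'
#' Bilinear interpolation at `n_samples` equally spaced points between `p0`
#' and `p1` (1-based (row, col) coordinates). `"max1"` divides by the
#' profile maximum; `"minmax"` maps the profile to `[0, 1]`.
#'
#' @param frame Numeric matrix.
#' @param p0,p1 Length-2 endpoints inside the frame.
#' @param n_samples Number of samples (>= 2).
#' @param normalize `"none"`, `"max1"`, or `"minmax"`.
#' @return Data.frame `t` (distance along the line, px) and `intensity`.
#' @export
line_profile <- function(frame, p0, p1, n_samples = 100,
                         normalize = c("none", "max1", "minmax")) {
  normalize <- match.arg(normalize)
  stopifnot(n_samples >= 2)
  inside <- function(p) all(p >= 1) && p[1] <= nrow(frame) && p[2] <= ncol(frame)
  if (!inside(p0) || !inside(p1)) stop("profile endpoints outside the frame")
  if (all(p0 == p1)) stop("zero-length profile line")
  s <- seq(0, 1, length.out = n_samples)
  r <- p0[1] + s * (p1[1] - p0[1])
  c <- p0[2] + s * (p1[2] - p0[2])
  v <- bilinear(frame, r, c)
  rng <- max(v) - min(v)
  tol <- 1e-12 * max(abs(v), 1)
  v <- switch(normalize,
    none = v,
    max1 = v / max(v),
    minmax = if (rng > tol) (v - min(v)) / rng
             else stop("constant profile cannot be min-max normalized")
  )
  data.frame(t = s * sqrt(sum((p1 - p0)^2)), intensity = v)
}

bilinear <- function(frame, r, c) {
  r0 <- pmin(pmax(floor(r), 1), nrow(frame) - 1); r1 <- r0 + 1
  c0 <- pmin(pmax(floor(c), 1), ncol(frame) - 1); c1 <- c0 + 1
  fr <- r - r0; fc <- c - c0
  frame[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    frame[cbind(r1, c0)] * fr * (1 - fc) +
    frame[cbind(r0, c1)] * (1 - fr) * fc +
    frame[cbind(r1, c1)] * fr * fc
}
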