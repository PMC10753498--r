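# Frame preprocessing: illumination (vignetting) correction, margin
# cropping, masked-median background subtraction, and the power log-log
# slope blur metric used for position QC.

#' Divide a frame by an illumination reference field
#'
#' @param frame Numeric matrix.
#' @param field Illumination field: same shape, values in `(0, 1]`, max 1.
#' @return Corrected frame (`frame / field`).
#' @export
correct_vignetting <- function(frame, field) {
  if (!all(dim(frame) == dim(field)))
    stop("frame and illumination field shapes differ")
  if (any(field <= 0))
    stop("illumination field must be strictly positive everywhere")
  frame / field
}

#' Margin crop specification
#'
#' Defaults are the screen's margins: 30 px top and left, 60 px right,
#' 160 px bottom, where residual vignetting survives the flat-field division.
#'
#' @param top,left,right,bottom Non-negative margins in pixels.
#' @return A `crop_spec` list.
#' @export
crop_spec <- function(top = 30, left = 30, right = 60, bottom = 160) {
  s <- list(top = top, left = left, right = right, bottom = bottom)
  stopifnot(all(unlist(s) >= 0))
  class(s) <- "crop_spec"
  s
}

#' Crop image margins
#'
#' @param frame Numeric matrix.
#' @param spec A [crop_spec()].
#' @return The cropped frame.
#' @export
crop_margins <- function(frame, spec = crop_spec()) {
  nr <- nrow(frame); nc <- ncol(frame)
  r0 <- spec$top + 1; r1 <- nr - spec$bottom
  c0 <- spec$left + 1; c1 <- nc - spec$right
  if (r0 > r1 || c0 > c1)
    stop("crop margins consume the whole image (", nr, "x", nc, ")")
  frame[r0:r1, c0:c1, drop = FALSE]
}

#' Masked-median background subtraction
#'
#' Estimates foreground by Gaussian smoothing plus a global Otsu threshold,
#' drops foreground objects smaller than `min_diameter` (equivalent
#' diameter), takes the median of the pixels outside the remaining mask as
#' the background level, and subtracts it, clipping at zero.
#'
#' @param frame Numeric matrix (cropped, vignetting-corrected).
#' @param smooth_fwhm Gaussian FWHM in pixels for the foreground mask.
#' @param min_diameter Minimum equivalent diameter of foreground objects.
#' @return List with `frame` (background-subtracted, non-negative) and
#'   `background_value`.
#' @export
subtract_background <- function(frame, smooth_fwhm = 6, min_diameter = 15) {
  if (max(frame) <= min(frame)) {
    # constant frame: the constant is the background
    bg <- frame[1]
    return(list(frame = frame - bg, background_value = bg))
  }
  sm <- smooth_gaussian(frame, fwhm = smooth_fwhm)
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  labels <- label_components(mask)
  props <- region_props(labels, frame, shape = FALSE)
  small <- props$label[props$equivalent_diameter < min_diameter]
  if (length(small)) mask[labels %in% small] <- FALSE
  if (all(mask)) {
    warning("foreground mask covers the whole frame; background from all pixels")
    bg <- median(frame)
  } else {
    bg <- median(frame[!mask])
  }
  list(frame = pmax(frame - bg, 0), background_value = bg)
}

#' Power log-log slope (blur metric)
#'
#' Least-squares slope of the log radially averaged 2D power spectrum
#' against log spatial frequency, excluding the zero frequency. Flat (white)
#' spectra give slopes near 0; blurred images give more negative slopes.
#' Radial averaging uses integer-radius annuli up to the Nyquist radius.
#'
#' @param frame Numeric matrix, at least 16 x 16.
#' @return The slope (dimensionless); `NaN` with a warning for a constant
#'   frame.
#' @export
power_loglog_slope <- function(frame) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr < 16 || nc < 16) stop("frame must be at least 16x16")
  if (max(frame) <= min(frame)) {
    warning("constant frame: power log-log slope undefined")
    return(NaN)
  }
  pw <- Mod(stats::fft(frame - mean(frame)))^2
  # integer radius in cycles-per-image units
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  r <- round(sqrt(outer(fy^2, fx^2, `+`)))
  rmax <- floor(min(nr, nc) / 2)
  sel <- r >= 1 & r <= rmax
  mean_pw <- tapply(pw[sel], r[sel], mean)
  radii <- as.numeric(names(mean_pw))
  ok <- mean_pw > 0
  if (sum(ok) < 2) {
    warning("degenerate spectrum: power log-log slope undefined")
    return(NaN)
  }
  x <- log(radii[ok] / min(nr, nc))  # cycles per pixel; shift does not affect slope
  y <- log(mean_pw[ok])
  unname(coef(stats::lm.fit(cbind(1, x), y))[2])
}
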