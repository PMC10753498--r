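#' @useDynLib fociscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm rpois runif sd nls coef aggregate
#' @importFrom utils read.csv write.csv head
NULL

#' Convert a Gaussian full width at half maximum to a standard deviation
#'
#' Smoothing in the screen pipeline is parameterised in FWHM pixels, the
#' convention of high-content tooling. `sigma = fwhm / (2 * sqrt(2 * log(2)))`.
#'
#' @param fwhm Full width at half maximum in pixels.
#' @return Standard deviation in pixels.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

gaussian_kernel <- function(sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-h, h)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of an image
#'
#' Separable Gaussian convolution with mirrored boundaries.
#'
#' @param img Numeric matrix.
#' @param fwhm Kernel full width at half maximum in pixels; ignored when
#'   `sigma` is given.
#' @param sigma Kernel standard deviation in pixels.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_gaussian <- function(img, fwhm = NULL, sigma = NULL) {
  stopifnot(is.matrix(img))
  if (is.null(sigma)) {
    stopifnot(!is.null(fwhm), fwhm > 0)
    sigma <- fwhm_to_sigma(fwhm)
  }
  cpp_sep_convolve(img, gaussian_kernel(sigma))
}

#' Discrete disk structuring element
#'
#' A "diameter d" element is the set of integer offsets within Euclidean
#' radius `floor(d / 2)` of the origin, the convention used throughout the
#' pipeline (diameter 6 gives radius 3).
#'
#' @param diameter Diameter in pixels.
#' @return Integer matrix of (row, col) offsets.
#' @export
disk_offsets <- function(diameter) {
  r <- floor(diameter / 2)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

gray_erode <- function(img, offsets) cpp_gray_morph(img, offsets, FALSE)
gray_dilate <- function(img, offsets) cpp_gray_morph(img, offsets, TRUE)

gray_open <- function(img, offsets) gray_dilate(gray_erode(img, offsets), -offsets)

#' White top-hat transform
#'
#' Image minus its morphological opening with a disk element; enhances bright
#' structures smaller than the element, the standard spot-enhancement step
#' before focus thresholding.
#'
#' @param img Numeric matrix.
#' @param diameter Disk diameter in pixels.
#' @return Matrix of the same shape, non-negative.
#' @export
white_tophat <- function(img, diameter) {
  off <- disk_offsets(diameter)
  img - gray_open(img, off)
}

#' Binary morphological opening of a mask
#'
#' @param mask Logical matrix.
#' @param diameter Disk diameter in pixels.
#' @return Logical matrix.
#' @export
binary_open <- function(mask, diameter) {
  off <- disk_offsets(diameter)
  gray_open(mask * 1, off) > 0.5
}

#' Label connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default).
#' @return Integer matrix; 0 is background, objects are numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  cpp_label(mask, as.integer(connectivity))
}

#' Global Otsu threshold on a 256-bin histogram
#'
#' Exhaustively maximizes the between-class variance over the 256-bin
#' histogram of `img` and returns the upper edge of the selected background
#' bin; foreground is `img > threshold`.
#'
#' @param img Numeric matrix or vector.
#' @return Threshold value, or `NA` for a constant input.
#' @export
otsu_threshold <- function(img) {
  x <- as.numeric(img)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(NA_real_)
  nb <- 256L
  breaks <- seq(lo, hi, length.out = nb + 1L)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), nb)
  h <- as.numeric(tabulate(bin, nbins = nb))  # numeric: counts products overflow int
  w <- cumsum(h)
  mids <- (breaks[-1] + breaks[-(nb + 1L)]) / 2
  m <- cumsum(h * mids)
  n <- w[nb]; mtot <- m[nb]
  w0 <- w[-nb]; m0 <- m[-nb]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m0 / w0
  mu1 <- (mtot - m0) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  k <- which.max(bcv)
  breaks[k + 1L]
}

#' Measure labeled objects
#'
#' Computes, for each labeled object, the features the screen's viability
#' filters use: area, centroid, intensity statistics on `img` within the
#' object, eccentricity from second central moments, and solidity (area over
#' convex-hull area, hull taken over pixel centers, counted on the grid).
#'
#' @param labels Integer label matrix.
#' @param img Numeric intensity matrix of the same shape.
#' @param shape Also compute eccentricity and solidity (needed for the
#'   viability filters; skipped for speed where only size and intensity
#'   matter, leaving those columns `NA`).
#' @return A data.frame with one row per object: `label, area, row, col,
#'   mean_intensity, sd_intensity, q75_intensity, integrated_intensity,
#'   max_intensity, equivalent_diameter, eccentricity, solidity`, plus a
#'   `pixels` list-column of linear pixel indices.
#' @export
region_props <- function(labels, img, shape = TRUE) {
  stopifnot(all(dim(labels) == dim(img)))
  idx <- which(labels > 0)
  if (length(idx) == 0) return(empty_props())
  lab <- labels[idx]
  nr <- nrow(labels)
  ri <- (idx - 1L) %% nr + 1L
  ci <- (idx - 1L) %/% nr + 1L
  vals <- img[idx]
  by_lab <- split(seq_along(idx), lab)
  ulab <- as.integer(names(by_lab))
  n <- length(by_lab)
  area <- lengths(by_lab)
  props <- data.frame(
    label = ulab, area = as.integer(area),
    row = vapply(by_lab, function(s) mean(ri[s]), 0),
    col = vapply(by_lab, function(s) mean(ci[s]), 0),
    mean_intensity = vapply(by_lab, function(s) mean(vals[s]), 0),
    sd_intensity = vapply(by_lab, function(s)
      if (length(s) > 1) sd(vals[s]) else 0, 0),
    q75_intensity = vapply(by_lab, function(s)
      unname(quantile(vals[s], 0.75)), 0),
    integrated_intensity = vapply(by_lab, function(s) sum(vals[s]), 0),
    max_intensity = vapply(by_lab, function(s) max(vals[s]), 0),
    equivalent_diameter = 2 * sqrt(area / pi),
    eccentricity = NA_real_, solidity = NA_real_
  )
  if (shape) {
    for (k in seq_len(n)) {
      s <- by_lab[[k]]
      r <- ri[s]; c <- ci[s]
      mr <- props$row[k]; mc <- props$col[k]
      # central second moments (+1/12 pixel-extent correction, standard in
      # region-props implementations, keeps 1-pixel objects non-degenerate)
      mu20 <- mean((r - mr)^2) + 1 / 12
      mu02 <- mean((c - mc)^2) + 1 / 12
      mu11 <- mean((r - mr) * (c - mc))
      tr <- mu20 + mu02
      det <- mu20 * mu02 - mu11^2
      disc <- sqrt(max(0, tr^2 / 4 - det))
      l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
      props$eccentricity[k] <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
      props$solidity[k] <- solidity_of(r, c)
    }
  }
  props$pixels <- lapply(by_lab, function(s) idx[s])
  props <- props[order(props$label), , drop = FALSE]  # split() orders by name
  rownames(props) <- NULL
  props
}

empty_props <- function() {
  d <- data.frame(
    label = integer(0), area = integer(0), row = numeric(0), col = numeric(0),
    mean_intensity = numeric(0), sd_intensity = numeric(0),
    q75_intensity = numeric(0), integrated_intensity = numeric(0),
    max_intensity = numeric(0), equivalent_diameter = numeric(0),
    eccentricity = numeric(0), solidity = numeric(0)
  )
  d$pixels <- list()
  d
}

solidity_of <- function(r, c) {
  n <- length(r)
  if (n <= 2) return(1)
  hull <- grDevices::chull(r, c)
  hx <- r[hull]; hy <- c[hull]
  if (length(hull) <= 2) return(1)
  # count grid pixels inside (or on) the hull within the bounding box
  rr <- seq(min(r), max(r)); cc <- seq(min(c), max(c))
  grid <- expand.grid(r = rr, c = cc)
  inside <- points_in_poly(grid$r, grid$c, hx, hy)
  hull_area <- sum(inside)
  if (hull_area <= 0) return(1)
  min(1, n / hull_area)
}

# even-odd rule point-in-polygon, boundary-inclusive within tolerance
points_in_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py))
    xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
    inside <- xor(inside, crosses & (px < xint))
    # distance of point to segment for boundary inclusion
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    on_edge <- on_edge | d2 < 1e-9
    j <- i
  }
  inside | on_edge
}
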