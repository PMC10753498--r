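# FRAP curve normalization and single-exponential recovery fitting.

#' Construct a FRAP curve
#'
#' @param time Time in seconds (bleach at the first non-negative time unless
#'   `bleach_index` is given).
#' @param intensity Mean ROI intensity.
#' @param bleach_index Index of the first post-bleach sample.
#' @return A `frap_curve` list.
#' @export
frap_curve <- function(time, intensity, bleach_index = which(time >= 0)[1]) {
  stopifnot(length(time) == length(intensity), !is.unsorted(time),
            !is.na(bleach_index), bleach_index >= 1)
  structure(list(time = time, intensity = intensity,
                 bleach_index = bleach_index), class = "frap_curve")
}

#' Min-max normalize a FRAP curve
#'
#' Maps intensities to `(I - min) / (max - min)` with `min` the first
#' post-bleach value and `max` the mean pre-bleach value (recorded in the
#' `normalization` attribute). Idempotent, and invariant to affine
#' transforms of the input.
#'
#' @param curve A `frap_curve`.
#' @return The normalized `frap_curve`.
#' @export
normalize_frap <- function(curve) {
  stopifnot(inherits(curve, "frap_curve"))
  b <- curve$bleach_index
  lo <- curve$intensity[b]
  hi <- if (b > 1) mean(curve$intensity[seq_len(b - 1)]) else max(curve$intensity)
  if (hi <= lo) stop("flat or inverted curve cannot be normalized")
  out <- frap_curve(curve$time, (curve$intensity - lo) / (hi - lo), b)
  attr(out, "normalization") <- list(min = lo, max = hi,
                                     convention = "min = first post-bleach, max = pre-bleach mean")
  out
}

#' Fit a single-exponential recovery model to a normalized FRAP curve
#'
#' Least squares of `I(t) = P * (1 - exp(-t / tau))` over the post-bleach
#' samples, `t` measured from the bleach. Initialized from a log-linear
#' estimate. Reports `tau`, the model half-time `tau * ln 2`, the empirical
#' half-time (first time the curve crosses `P / 2`, interpolated), the
#' plateau `P`, and the residual RMS.
#'
#' @param curve A normalized `frap_curve` with at least 5 post-bleach points.
#' @return A `frap_fit` list: `tau`, `half_time`, `half_time_empirical`,
#'   `plateau`, `rms`, `converged`.
#' @export
fit_frap <- function(curve) {
  stopifnot(inherits(curve, "frap_curve"))
  b <- curve$bleach_index
  t <- curve$time[b:length(curve$time)]
  t <- t - t[1]
  y <- curve$intensity[b:length(curve$intensity)]
  if (length(t) < 5) stop("need >= 5 post-bleach points")
  # log-linear initialization: log(1 - y/P0) = -t / tau
  P0 <- max(mean(y[t >= quantile(t, 0.8)]), 1e-3)
  sel <- y < P0 & y > 0 & t > 0
  tau0 <- if (sum(sel) >= 2) {
    z <- log(1 - pmin(y[sel] / P0, 1 - 1e-6))
    -1 / coef(stats::lm.fit(cbind(1, t[sel]), z))[2]
  } else max(t) / 3
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t) / 3
  fit <- tryCatch(
    nls(y ~ P * (1 - exp(-t / tau)), start = list(P = P0, tau = tau0)),
    error = function(e) tryCatch(
      # fall back to bounded port iterations; accept its "singular
      # convergence" near-solutions instead of failing outright
      suppressWarnings(
        nls(y ~ P * (1 - exp(-t / tau)), start = list(P = P0, tau = tau0),
            lower = c(P = 1e-6, tau = 1e-6), algorithm = "port",
            control = stats::nls.control(warnOnly = TRUE))),
      error = function(e2) NULL
    )
  )
  if (is.null(fit)) {
    res <- y - P0 * (1 - exp(-t / tau0))
    return(structure(list(tau = tau0, half_time = tau0 * log(2),
                          half_time_empirical = empirical_half_time(t, y, P0),
                          plateau = P0, rms = sqrt(mean(res^2)),
                          converged = FALSE), class = "frap_fit"))
  }
  p <- coef(fit)
  res <- y - p[["P"]] * (1 - exp(-t / p[["tau"]]))
  structure(list(tau = p[["tau"]], half_time = p[["tau"]] * log(2),
                 half_time_empirical = empirical_half_time(t, y, p[["P"]]),
                 plateau = p[["P"]], rms = sqrt(mean(res^2)),
                 converged = TRUE), class = "frap_fit")
}

empirical_half_time <- function(t, y, P) {
  target <- P / 2
  above <- which(y >= target)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1) return(t[1])
  # linear interpolation between the straddling samples
  t[i - 1] + (target - y[i - 1]) * (t[i] - t[i - 1]) / (y[i] - y[i - 1])
}

#' Fit many FRAP curves and average the recovered time constants
#'
#' Normalizes (unless already normalized) and fits each curve, returning
#' per-curve fits plus the mean and standard deviation of tau, the
#' per-curve-fit-then-average convention.
#'
#' @param curves List of `frap_curve` objects.
#' @param normalize Normalize each curve first.
#' @return List `fits`, `tau_mean`, `tau_sd`, `half_time_mean`.
#' @export
fit_frap_batch <- function(curves, normalize = TRUE) {
  fits <- lapply(curves, function(cu) {
    if (normalize) cu <- normalize_frap(cu)
    fit_frap(cu)
  })
  taus <- vapply(fits, `[[`, 0, "tau")
  list(fits = fits, tau_mean = mean(taus), tau_sd = sd(taus),
       half_time_mean = mean(taus) * log(2))
}
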