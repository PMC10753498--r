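# Synthetic time-lapse scenes with per-cell ground truth.
#
# The generator emulates the statistical structure the screen pipeline
# assumes: roughly elliptical nuclei doing a Gaussian random walk, a
# subpopulation entering a late-S window during which a Poisson number of
# bright foci appears for a bounded lifetime, radially asymmetric vignetting,
# substrate autofluorescence decaying exponentially over frames
# (photobleaching), small bright round dead/mitotic cells, and micronucleus
# protrusions. All intensities are emitted in [0, 1] so the screen's
# arbitrary-unit thresholds (0.004, 0.014) apply directly.

#' Parameters of a synthetic time-lapse scene
#'
#' Defaults encode the system the live-imaging experiments describe: 2.7
#' bodies per body-positive cell on average, body lifetime 48 +/- 30 min,
#' 10 min frame interval, 0.8 um/px (20x objective on a 16 um-pixel EMCCD),
#' frame-to-frame drift well under the 15 px tracking gate.
#'
#' @param image_shape Integer (rows, cols) in pixels.
#' @param pixel_size Pixel size in um/px.
#' @param n_frames Number of frames.
#' @param frame_interval Minutes between frames.
#' @param n_cells Number of cells placed at frame 1.
#' @param nucleus_radius_mean,nucleus_radius_sd Half-max nucleus radius (px).
#' @param nucleus_amplitude Peak nuclear intensity above background.
#' @param cell_drift_sd Random-walk step standard deviation (px/frame).
#' @param foci_rate_lambda Expected foci per body-positive cell (Poisson).
#' @param foci_lifetime_mean,foci_lifetime_sd Body lifetime (min).
#' @param late_s_fraction Fraction of normal cells given a body window.
#' @param focus_radius Focus Gaussian sigma (px).
#' @param focus_amplitude Focus peak intensity above the nuclear level.
#' @param background_level Substrate autofluorescence at frame 1.
#' @param bleach_halflife Background half-life in frames (`Inf` disables).
#' @param vignette_strength Vignetting depth in `[0, 1)`.
#' @param vignette_asymmetry Fractional (row, col) offset of the vignette peak.
#' @param dead_cell_fraction Fraction of cells rendered dead/mitotic
#'   (small, bright, round; the two classes are split evenly).
#' @param micronucleus_fraction Fraction of normal cells with a micronucleus
#'   protrusion.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param foci_count `NA` (default) draws each body-positive cell's focus
#'   count from a Poisson with mean `foci_rate_lambda` (capped at 10);
#'   an integer plants exactly that many foci per positive cell.
#' @param seed Integer seed; every random choice derives from it.
#' @return A validated `scene_params` list.
#' @export
scene_params <- function(image_shape = c(256L, 256L),
                         pixel_size = 0.8,
                         n_frames = 25L,
                         frame_interval = 10,
                         n_cells = 9L,
                         nucleus_radius_mean = 22,
                         nucleus_radius_sd = 1.5,
                         nucleus_amplitude = 0.35,
                         cell_drift_sd = 2,
                         foci_rate_lambda = 2.7,
                         foci_lifetime_mean = 48,
                         foci_lifetime_sd = 30,
                         late_s_fraction = 0.3,
                         focus_radius = 2,
                         focus_amplitude = 0.05,
                         background_level = 0.1,
                         bleach_halflife = 40,
                         vignette_strength = 0.3,
                         vignette_asymmetry = c(0.05, 0.08),
                         dead_cell_fraction = 0.05,
                         micronucleus_fraction = 0.03,
                         noise_sd = 0.004,
                         foci_count = NA,
                         seed = 1L) {
  p <- list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    n_frames = as.integer(n_frames), frame_interval = frame_interval,
    n_cells = as.integer(n_cells),
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd,
    nucleus_amplitude = nucleus_amplitude,
    cell_drift_sd = cell_drift_sd,
    foci_rate_lambda = foci_rate_lambda,
    foci_lifetime_mean = foci_lifetime_mean,
    foci_lifetime_sd = foci_lifetime_sd,
    late_s_fraction = late_s_fraction,
    focus_radius = focus_radius, focus_amplitude = focus_amplitude,
    background_level = background_level, bleach_halflife = bleach_halflife,
    vignette_strength = vignette_strength,
    vignette_asymmetry = vignette_asymmetry,
    dead_cell_fraction = dead_cell_fraction,
    micronucleus_fraction = micronucleus_fraction,
    noise_sd = noise_sd, foci_count = foci_count, seed = as.integer(seed)
  )
  stopifnot(
    length(p$image_shape) == 2, all(p$image_shape >= 16),
    p$pixel_size > 0, p$n_frames >= 1, p$frame_interval > 0, p$n_cells >= 0,
    p$nucleus_radius_mean > 0, p$nucleus_radius_sd >= 0,
    p$foci_rate_lambda >= 0,
    p$late_s_fraction >= 0, p$late_s_fraction <= 1,
    p$dead_cell_fraction >= 0, p$dead_cell_fraction <= 1,
    p$micronucleus_fraction >= 0, p$micronucleus_fraction <= 1,
    p$vignette_strength >= 0, p$vignette_strength < 1,
    p$background_level >= 0, p$noise_sd >= 0, p$bleach_halflife > 0
  )
  class(p) <- "scene_params"
  p
}

# run `expr` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Analytic illumination (vignetting) reference field
#'
#' A smooth radial fall-off, `1 - strength * (r / r_max)^2`, with the peak
#' optionally shifted off-center to mimic the slightly asymmetric vignetting
#' of real acquisition optics. The maximum is exactly 1 and the minimum is at
#' least `1 - strength`. The field is deterministic; `seed` is accepted for
#' interface symmetry and ignored.
#'
#' @param shape Integer (rows, cols).
#' @param strength Depth of the fall-off, in `[0, 1)`.
#' @param asymmetry Length-2 fractional offset of the peak from the center.
#' @param seed Ignored.
#' @return Numeric matrix with values in `(0, 1]`, max exactly 1.
#' @export
generate_illumination_field <- function(shape, strength = 0.3,
                                        asymmetry = c(0, 0), seed = NULL) {
  if (strength >= 1 || strength < 0)
    stop("vignetting `strength` must lie in [0, 1): values >= 1 would zero out pixels")
  nr <- shape[1]; nc <- shape[2]
  cy <- (nr + 1) / 2 + asymmetry[1] * nr
  cx <- (nc + 1) / 2 + asymmetry[2] * nc
  r <- outer(seq_len(nr) - cy, seq_len(nc) - cx, function(a, b) sqrt(a^2 + b^2))
  rmax <- max(r)
  if (rmax == 0) return(matrix(1, nr, nc))
  field <- 1 - strength * (r / rmax)^2
  field / max(field)  # max exactly 1 even when the peak is off-grid
}

render_nucleus_patch <- function(frame, cy, cx, ry, rx, theta, amplitude,
                                 order = 2, truncate = 2.2) {
  # anisotropic super-Gaussian, exp(-log(2) * q^(2*order)) with
  # q^2 = (u/ry)^2 + (v/rx)^2: half-max contour exactly at radii (ry, rx).
  # order 2 gives the flat-topped plateau of an interphase nucleus; order 1
  # is an ordinary Gaussian (used for foci).
  nr <- nrow(frame); nc <- ncol(frame)
  half <- ceiling(truncate * max(ry, rx))
  r0 <- max(1, floor(cy - half)); r1 <- min(nr, ceiling(cy + half))
  c0 <- max(1, floor(cx - half)); c1 <- min(nc, ceiling(cx + half))
  if (r0 > r1 || c0 > c1) return(frame)
  rr <- r0:r1; cc <- c0:c1
  dy <- outer(rr - cy, rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - cx)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  q2 <- (u / ry)^2 + (v / rx)^2
  g <- exp(-log(2) * q2^order)
  frame[rr, cc] <- frame[rr, cc] + amplitude * g
  frame
}

sample_cells <- function(p, packed = TRUE) {
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  n <- p$n_cells
  if (n == 0) {
    return(data.frame(cell = integer(0), y0 = numeric(0), x0 = numeric(0),
                      ry = numeric(0), rx = numeric(0), theta = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  rmax <- p$nucleus_radius_mean + 3 * p$nucleus_radius_sd
  if (packed && n * (2 * rmax)^2 > 0.7 * nr * nc)
    stop("packing error: n_cells = ", n, " cells of radius ~", round(rmax),
         " px do not fit a ", nr, "x", nc, " image")
  margin <- min(rmax + 2, nr / 4, nc / 4)
  placed <- matrix(NA_real_, 0, 2)
  sep2 <- (2.9 * p$nucleus_radius_mean)^2
  for (i in seq_len(n)) {
    if (!packed) {
      placed <- rbind(placed, c(runif(1, margin, nr - margin),
                                runif(1, margin, nc - margin)))
      next
    }
    best <- NULL; best_d <- -Inf
    for (try in 1:500) {
      y <- runif(1, margin, nr - margin); x <- runif(1, margin, nc - margin)
      d <- if (nrow(placed) == 0) Inf else
        min((placed[, 1] - y)^2 + (placed[, 2] - x)^2)
      if (d > sep2) { best <- c(y, x); break }
      if (d > best_d) { best_d <- d; best <- c(y, x) }
    }
    # densest scenes fall back to the best-spread candidate rather than fail
    placed <- rbind(placed, best)
  }
  # viability classes: dead/mitotic split evenly from dead_cell_fraction
  u <- runif(n)
  cls <- ifelse(u < p$dead_cell_fraction / 2, "dead",
         ifelse(u < p$dead_cell_fraction, "mitotic", "normal"))
  micro <- runif(n) < p$micronucleus_fraction & cls == "normal"
  cls[micro] <- "micronucleated"
  base_r <- pmax(4, rnorm(n, p$nucleus_radius_mean, p$nucleus_radius_sd))
  aspect <- runif(n, 1.05, 1.5)
  ry <- base_r * sqrt(aspect); rx <- base_r / sqrt(aspect)
  # dead/mitotic: smaller and round, but above the segmentation size gate
  small <- cls %in% c("dead", "mitotic")
  ry[small] <- base_r[small] * 0.75; rx[small] <- base_r[small] * 0.75
  data.frame(cell = seq_len(n), y0 = placed[, 1], x0 = placed[, 2],
             ry = ry, rx = rx, theta = runif(n, 0, pi), class = cls,
             stringsAsFactors = FALSE)
}

sample_windows <- function(cells, p) {
  n <- nrow(cells)
  win <- data.frame(cell = cells$cell, positive = logical(n),
                    start = rep(NA_integer_, n), end = rep(NA_integer_, n),
                    n_foci = integer(n))
  if (n == 0) return(win)
  eligible <- cells$class %in% c("normal", "micronucleated")
  win$positive <- eligible & runif(n) < p$late_s_fraction
  for (i in which(win$positive)) {
    life_min <- max(p$frame_interval, rnorm(1, p$foci_lifetime_mean, p$foci_lifetime_sd))
    len <- max(1L, as.integer(round(life_min / p$frame_interval)))
    start <- sample.int(p$n_frames, 1)
    win$start[i] <- start
    win$end[i] <- min(p$n_frames, start + len - 1L)
    win$n_foci[i] <- if (is.na(p$foci_count)) min(10L, rpois(1, p$foci_rate_lambda))
                     else as.integer(p$foci_count)
  }
  win
}

#' Render a synthetic time lapse with ground truth
#'
#' @param params A [scene_params()] object.
#' @param seed Optional integer overriding `params$seed`.
#' @param render If `FALSE`, skip pixel rendering and return ground truth
#'   only (fast mode for large score-calibration simulations).
#' @return A list with `frames` (list of matrices, or `NULL` when
#'   `render = FALSE`), `ground_truth` (see below), `params`, and the
#'   illumination `field`. `ground_truth` holds `cells` (one row per cell:
#'   class, body window, true focus count, shape), `tracks` (cell x frame
#'   centroids with per-frame true focus counts) and `foci` (one row per
#'   focus per frame with its centroid).
#' @export
render_timelapse <- function(params, seed = NULL, render = TRUE) {
  p <- params
  stopifnot(inherits(p, "scene_params"))
  if (!is.null(seed)) p$seed <- as.integer(seed)
  with_seed(p$seed, {
    nr <- p$image_shape[1]; nc <- p$image_shape[2]
    cells <- sample_cells(p, packed = render)
    win <- sample_windows(cells, p)
    n <- nrow(cells)
    # random-walk centroids, reflected at a margin
    margin <- 4
    ys <- matrix(0, n, p$n_frames); xs <- matrix(0, n, p$n_frames)
    if (n > 0) {
      stepy <- matrix(rnorm(n * p$n_frames, 0, p$cell_drift_sd), n)
      stepx <- matrix(rnorm(n * p$n_frames, 0, p$cell_drift_sd), n)
      stepy[, 1] <- 0; stepx[, 1] <- 0
      ys <- cells$y0 + t(apply(stepy, 1, cumsum))
      xs <- cells$x0 + t(apply(stepx, 1, cumsum))
      ys <- pmin(pmax(ys, margin), nr - margin)
      xs <- pmin(pmax(xs, margin), nc - margin)
      dim(ys) <- dim(xs) <- c(n, p$n_frames)
    }
    # foci offsets relative to the nucleus center, inside the half-max mask
    # distinct bodies: rejection-sample offsets at least 6 focus radii apart
    # (resolvable under the detection pipeline's own smoothing scale)
    min_sep2 <- (6 * p$focus_radius)^2
    foci_off <- lapply(seq_len(n), function(i) {
      k <- win$n_foci[i]
      if (!isTRUE(win$positive[i]) || k == 0) return(NULL)
      th <- cells$theta[i]
      pts <- matrix(NA_real_, 0, 2)
      for (s in seq_len(k)) {
        for (try in 1:200) {
          ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * 0.6
          du <- rad * cos(ang) * cells$ry[i]; dv <- rad * sin(ang) * cells$rx[i]
          cand <- c(du * cos(th) - dv * sin(th), du * sin(th) + dv * cos(th))
          if (nrow(pts) == 0 ||
              min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= min_sep2) break
        }
        pts <- rbind(pts, cand)
      }
      colnames(pts) <- c("dy", "dx")
      pts
    })

    nf <- p$n_frames
    if (n > 0) {
      frame_seq <- rep(seq_len(nf), n)
      cell_seq <- rep(seq_len(n), each = nf)
      in_win <- !is.na(win$start[cell_seq]) &
        frame_seq >= win$start[cell_seq] & frame_seq <= win$end[cell_seq]
      tracks <- data.frame(cell = cell_seq, frame = frame_seq,
                           y = as.vector(t(ys)), x = as.vector(t(xs)),
                           class = cells$class[cell_seq],
                           n_foci = ifelse(in_win, win$n_foci[cell_seq], 0L),
                           stringsAsFactors = FALSE)
    } else {
      tracks <- data.frame(cell = integer(0), frame = integer(0), y = numeric(0),
                           x = numeric(0), class = character(0), n_foci = integer(0))
    }
    has_foci <- which(!vapply(foci_off, is.null, TRUE))
    if (length(has_foci)) {
      per_cell <- lapply(has_foci, function(i) {
        off <- foci_off[[i]]
        k <- nrow(off)
        fr <- seq(win$start[i], win$end[i])
        m <- length(fr)
        list(cell = rep.int(i, k * m), frame = rep(fr, each = k),
             focus = rep.int(seq_len(k), m),
             y = rep(ys[i, fr], each = k) + rep.int(off[, "dy"], m),
             x = rep(xs[i, fr], each = k) + rep.int(off[, "dx"], m))
      })
      foci <- data.frame(
        cell = unlist(lapply(per_cell, `[[`, "cell")),
        frame = unlist(lapply(per_cell, `[[`, "frame")),
        focus = unlist(lapply(per_cell, `[[`, "focus")),
        y = unlist(lapply(per_cell, `[[`, "y")),
        x = unlist(lapply(per_cell, `[[`, "x")))
    } else {
      foci <- data.frame(cell = integer(0), frame = integer(0),
                         focus = integer(0), y = numeric(0), x = numeric(0))
    }

    gt_cells <- cbind(cells, win[, c("positive", "start", "end", "n_foci")])
    field <- generate_illumination_field(p$image_shape, p$vignette_strength,
                                         p$vignette_asymmetry)
    frames <- NULL
    if (render) {
      noise <- if (p$noise_sd > 0)
        matrix(rnorm(nr * nc * p$n_frames, 0, p$noise_sd), nr * nc, p$n_frames)
      frames <- vector("list", p$n_frames)
      for (f in seq_len(p$n_frames)) {
        bg <- p$background_level * 2^(-(f - 1) / p$bleach_halflife)
        img <- matrix(bg, nr, nc)
        for (i in seq_len(n)) {
          amp <- p$nucleus_amplitude
          if (cells$class[i] %in% c("dead", "mitotic")) amp <- amp * 2.5
          img <- render_nucleus_patch(img, ys[i, f], xs[i, f],
                                      cells$ry[i], cells$rx[i],
                                      cells$theta[i], amp)
          if (cells$class[i] == "micronucleated") {
            # small protrusion at the nucleus edge, along the major axis
            my <- ys[i, f] + 1.12 * cells$ry[i] * cos(cells$theta[i])
            mx <- xs[i, f] + 1.12 * cells$ry[i] * sin(cells$theta[i])
            img <- render_nucleus_patch(img, my, mx, 2.5, 2.5, 0, amp * 0.9)
          }
        }
        ff <- foci[foci$frame == f, , drop = FALSE]
        for (k in seq_len(nrow(ff)))
          img <- render_nucleus_patch(img, ff$y[k], ff$x[k],
                                      p$focus_radius, p$focus_radius, 0,
                                      p$focus_amplitude, order = 1,
                                      truncate = 4)
        img <- img * field
        if (p$noise_sd > 0) img <- img + matrix(noise[, f], nr, nc)
        frames[[f]] <- pmin(pmax(img, 0), 1)
      }
    }
    tl <- if (is.null(frames)) NULL else
      structure(frames, pixel_size = p$pixel_size,
                frame_interval = p$frame_interval, class = "timelapse")
    list(frames = tl,
         ground_truth = structure(list(cells = gt_cells, tracks = tracks,
                                       foci = foci),
                                  class = "ground_truth"),
         field = field, params = p)
  })
}

#' Simulate a fluorescence-recovery (FRAP) curve
#'
#' Pre-bleach samples (negative times) sit at 1; from the bleach at `t = 0`
#' the signal recovers as `plateau * (1 - exp(-t / tau))`, plus optional
#' Gaussian noise.
#'
#' @param tau Recovery time constant in seconds (> 0).
#' @param plateau Mobile-fraction plateau in `[0, 1]`.
#' @param times Sorted time vector in seconds, starting pre-bleach (< 0).
#' @param noise_sd Additive noise sd.
#' @param seed Integer seed.
#' @return A `frap_curve`: list with `time`, `intensity`, `bleach_index`.
#' @export
simulate_frap_curve <- function(tau, plateau = 0.8,
                                times = c(seq(-10, -2, by = 2), seq(0, 120, by = 1)),
                                noise_sd = 0, seed = 1L) {
  if (tau <= 0) stop("`tau` must be > 0")
  stopifnot(plateau >= 0, plateau <= 1, !is.unsorted(times))
  I <- ifelse(times < 0, 1, plateau * (1 - exp(-pmax(times, 0) / tau)))
  if (noise_sd > 0) I <- with_seed(seed, I + rnorm(length(I), 0, noise_sd))
  structure(list(time = times, intensity = I,
                 bleach_index = which(times >= 0)[1]),
            class = "frap_curve")
}

#' Write ground truth as CSV (0-based pixel coordinates)
#'
#' @param gt A `ground_truth` object.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  d <- gt$tracks
  out <- data.frame(cell_id = d$cell, frame = d$frame - 1L,
                    x = d$x - 1, y = d$y - 1, class = d$class,
                    n_foci = d$n_foci)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
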