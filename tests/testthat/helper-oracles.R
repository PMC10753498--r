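# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no shared helpers): plain loops and enumeration only.

# Otsu: exhaustive between-class variance over the same 256-bin histogram.
oracle_otsu <- function(x) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(NA_real_)
  nb <- 256L
  breaks <- seq(lo, hi, length.out = nb + 1L)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), nb)
  h <- as.numeric(tabulate(bin, nbins = nb))
  mids <- (breaks[-1] + breaks[-(nb + 1L)]) / 2
  best_k <- NA; best_v <- -Inf
  for (k in 1:(nb - 1)) {
    w0 <- sum(h[1:k]); w1 <- sum(h[(k + 1):nb])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * mids[1:k]) / w0
    mu1 <- sum(h[(k + 1):nb] * mids[(k + 1):nb]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v) { best_v <- v; best_k <- k }
  }
  breaks[best_k + 1L]
}

# Plateau-maxima of an image: connected regions of equal value with no
# higher 8-neighbor. Returns a list of (pixels, value, rep = min linear index).
oracle_plateau_maxima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  seen <- matrix(FALSE, nr, nc)
  out <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (seen[i, j]) next
    v <- img[i, j]
    # flood the equal-value region
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    px <- list(); is_max <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      px[[length(px) + 1]] <- p
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (img[ii, jj] > v) is_max <- FALSE
        if (img[ii, jj] == v && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
    if (is_max) {
      m <- do.call(rbind, px)
      out[[length(out) + 1]] <- list(
        pixels = m, value = v,
        rep = min((m[, 2] - 1) * nr + m[, 1]))
    }
  }
  out
}

# Brute-force prominence by explicit level sets, with the package's stated
# tie rule: a plateau maximum "dies" at the highest level v at which the
# connected component of {img >= v} containing it also contains a strictly
# higher pixel, or an equal-height plateau maximum with a smaller
# representative index; the overall winner gets value - min(img).
oracle_prominences <- function(img) {
  nr <- nrow(img)
  maxima <- oracle_plateau_maxima(img)
  levels <- sort(unique(as.numeric(img)), decreasing = TRUE)
  comp_at <- function(v) {
    mask <- img >= v
    lab <- matrix(0L, nr, ncol(img))
    nxt <- 0L
    for (j in seq_len(ncol(img))) for (i in seq_len(nr)) {
      if (!mask[i, j] || lab[i, j] > 0) next
      nxt <- nxt + 1L
      stack <- list(c(i, j)); lab[i, j] <- nxt
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > ncol(img)) next
          if (mask[ii, jj] && lab[ii, jj] == 0) {
            lab[ii, jj] <- nxt
            stack[[length(stack) + 1]] <- c(ii, jj)
          }
        }
      }
    }
    lab
  }
  vmin <- min(img)
  res <- data.frame(rep = vapply(maxima, `[[`, 0, "rep"),
                    value = vapply(maxima, `[[`, 0, "value"),
                    prominence = NA_real_)
  for (k in seq_along(maxima)) {
    m <- maxima[[k]]
    saddle <- NA_real_
    for (v in levels) {
      if (v > m$value) next
      lab <- comp_at(v)
      own <- lab[m$pixels[1, 1], m$pixels[1, 2]]
      in_comp <- which(lab == own)
      if (any(img[in_comp] > m$value)) { saddle <- v; break }
      # equal-height plateau max with smaller representative index?
      rivals <- res$rep[res$value == m$value & res$rep < m$rep]
      if (length(rivals)) {
        ri <- (rivals - 1) %% nr + 1
        ci <- (rivals - 1) %/% nr + 1
        if (any(lab[cbind(ri, ci)] == own)) { saddle <- v; break }
      }
    }
    res$prominence[k] <- if (is.na(saddle)) m$value - vmin else m$value - saddle
  }
  res
}

# Binary closing of a 0/1 vector done literally as pad -> dilate -> erode ->
# crop, with the two-element structuring element {0, +1} whose closing fills
# exactly one-frame gaps (a centered three-element SE would also bridge
# two-frame gaps, which the gap-filling contract excludes).
oracle_close_positivity <- function(pos) {
  n <- length(pos)
  p <- c(0L, 0L, pos, 0L, 0L)
  m <- length(p)
  d <- integer(m)
  for (i in 1:(m - 1)) d[i] <- max(p[i], p[i + 1])      # dilation by {0,+1}
  e <- integer(m)
  for (i in 2:m) e[i] <- min(d[i - 1], d[i])            # erosion by {0,+1}
  e[3:(n + 2)]
}

# Manders M1 by an explicit per-pixel loop.
oracle_manders <- function(ch1, ch2, thr = 0) {
  num <- 0; den <- 0
  for (j in seq_len(ncol(ch1))) for (i in seq_len(nrow(ch1))) {
    den <- den + ch1[i, j]
    if (ch2[i, j] > thr) num <- num + ch1[i, j]
  }
  if (den == 0) NA_real_ else num / den
}

# Exhaustive maximum-total-overlap one-to-one assignment over candidate
# pairs (columns prev, curr, overlap). Returns the best total overlap.
oracle_best_assignment <- function(cand) {
  if (nrow(cand) == 0) return(0)
  best <- 0
  recurse <- function(rows, used_p, used_c, total) {
    if (total > best) best <<- total
    if (!length(rows)) return()
    r <- rows[1]; rest <- rows[-1]
    # skip this candidate
    recurse(rest, used_p, used_c, total)
    # or take it if free
    if (!(cand$prev[r] %in% used_p) && !(cand$curr[r] %in% used_c))
      recurse(rest, c(used_p, cand$prev[r]), c(used_c, cand$curr[r]),
              total + cand$overlap[r])
  }
  recurse(seq_len(nrow(cand)), integer(0), integer(0), 0)
  best
}

# Build a nucleus-object table from a label matrix, for tracking tests.
objects_from_labels <- function(labels, img = NULL) {
  if (is.null(img)) img <- matrix(1, nrow(labels), ncol(labels))
  region_props(labels, img, shape = FALSE)
}

# Place disk-shaped objects at given centers; returns the label matrix.
disks_matrix <- function(shape, centers, radius) {
  lab <- matrix(0L, shape[1], shape[2])
  for (k in seq_len(nrow(centers))) {
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
      if ((i - centers[k, 1])^2 + (j - centers[k, 2])^2 <= radius^2)
        lab[i, j] <- k
    }
  }
  lab
}

# centers of non-interpenetrating objects (the overlap tracker's regime)
separated_centers <- function(n, lo, hi, min_sep) {
  repeat {
    c0 <- cbind(runif(n, lo, hi), runif(n, lo, hi))
    ok <- TRUE
    if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (sum((c0[i, ] - c0[j, ])^2) < min_sep^2) ok <- FALSE
    if (ok) return(c0)
  }
}
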