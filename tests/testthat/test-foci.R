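scene_with_foci <- function(seed, foci_count = 3, amplitude = 0.05,
                            n_cells = 5, micronucleus_fraction = 0) {
  p <- scene_params(n_cells = n_cells, n_frames = 1, late_s_fraction = 1,
                    foci_count = foci_count, focus_amplitude = amplitude,
                    dead_cell_fraction = 0,
                    micronucleus_fraction = micronucleus_fraction, seed = seed)
  sc <- render_timelapse(p)
  frame <- subtract_background(correct_vignetting(sc$frames[[1]], sc$field))$frame
  list(frame = frame, gt = sc$ground_truth,
       nuclei = segment_nuclei(frame, segmentation_profile("primary")))
}

test_that("detect_foci finds planted foci and nothing else", {
  s0 <- scene_with_foci(41, amplitude = 0)
  expect_equal(nrow(detect_foci(s0$frame, s0$nuclei)), 0)
  expect_equal(nrow(detect_foci(s0$frame, s0$nuclei[0, ])), 0)
  s <- scene_with_foci(42)
  det <- detect_foci(s$frame, s$nuclei, foci_profile("primary"))
  tru <- s$gt$foci
  expect_equal(nrow(det), nrow(tru))
  # every true focus has a detection within 2 px: thresholded top-hat
  # centroids carry a pixel-scale bias from the sloped nuclear background
  # under each focus (worst near the nuclear rim), and sub-pixel
  # localization is out of scope
  for (k in seq_len(nrow(tru))) {
    d <- sqrt((det$row - tru$y[k])^2 + (det$col - tru$x[k])^2)
    expect_lt(min(d), 2)
  }
  # every focus centroid belongs to exactly one segmented nucleus
  expect_true(all(det$nucleus %in% s$nuclei$label))
})

test_that("focus count is monotone non-increasing in the manual threshold", {
  s <- scene_with_foci(43)
  counts <- vapply(c(0.001, 0.004, 0.01, 0.02, 0.05), function(th)
    nrow(detect_foci(s$frame, s$nuclei,
                     foci_profile("primary", manual_threshold = th))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("mask opening removes micronucleus protrusions before detection", {
  # plateau nucleus with a narrow 4-px-wide protrusion carrying a focus
  frame <- matrix(0.02, 96, 96)
  disk <- disks_matrix(c(96, 96), rbind(c(48, 44)), 19) > 0
  frame[disk] <- 0.35
  frame[47:50, 62:72] <- 0.35                 # 4-px-wide protrusion
  frame <- fociscreen:::render_nucleus_patch(frame, 48.5, 68, 2, 2, 0, 0.05,
                                             order = 1, truncate = 4)  # focus on it
  nuc_p <- segment_nuclei(frame, segmentation_profile("primary"))
  expect_equal(nrow(nuc_p), 1)
  on_protrusion <- function(d) any(abs(d$row - 48.5) < 3 & abs(d$col - 68) < 3)
  det_p <- detect_foci(frame, nuc_p, foci_profile("primary"))
  expect_false(on_protrusion(det_p))    # opening strips the protrusion
  nuc_s <- segment_nuclei(frame, segmentation_profile("secondary"))
  expect_equal(nrow(nuc_s), 1)
  det_s <- detect_foci(frame, nuc_s, foci_profile("secondary"))
  expect_true(on_protrusion(det_s))     # no opening in the secondary profile
})

test_that("find_maxima matches its definition on constructed images", {
  expect_equal(nrow(find_maxima(matrix(5, 10, 10), 1)), 0)
  two <- outer(1:64, 1:64, function(r, c)
    100 * exp(-((r - 20)^2 + (c - 20)^2) / 8) +
    100 * exp(-((r - 45)^2 + (c - 45)^2) / 8))
  expect_equal(nrow(find_maxima(two, 80)), 2)
  # a connecting ridge turns the lower-persistence peak's prominence into
  # (peak - saddle); with equal peaks the survivor keeps peak - min
  ridge <- two
  path <- cbind(round(seq(20, 45, length.out = 26)),
                round(seq(20, 45, length.out = 26)))
  ridge[path] <- pmax(ridge[path], 30)
  pk <- fociscreen:::cpp_peaks(ridge)
  pk <- pk[order(-pk$prominence), ]
  expect_equal(pk$prominence[1], 100, tolerance = 1e-6)
  expect_equal(pk$prominence[2], 70, tolerance = 0.02)   # 100 - saddle(30)
  expect_equal(nrow(find_maxima(ridge, 80)), 1)
  ridge90 <- two
  ridge90[path] <- pmax(ridge90[path], 90)
  expect_equal(nrow(find_maxima(ridge90, 80)), 1)
  # plateau: a flat-topped square yields one maximum at its centroid
  plat <- matrix(0, 32, 32); plat[10:13, 20:23] <- 7
  m <- find_maxima(plat, 5)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$row, m$col), c(11.5, 21.5))
})

test_that("find_maxima agrees with the brute-force prominence oracle", {
  set.seed(99)
  for (rep in 1:12) {
    img <- matrix(sample(0:9, 16 * 16, replace = TRUE), 16)
    oracle <- oracle_prominences(img)
    for (prom in c(1, 3, 5, 8)) {
      got <- find_maxima(img, prom)
      want <- oracle[oracle$prominence >= prom, ]
      expect_equal(nrow(got), nrow(want),
                   info = sprintf("rep %d prom %d", rep, prom))
      expect_equal(sort(got$prominence), sort(want$prominence),
                   info = sprintf("rep %d prom %d", rep, prom))
    }
  }
})
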