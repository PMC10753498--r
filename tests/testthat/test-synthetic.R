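test_that("illumination field honors its normalization contract", {
  f0 <- generate_illumination_field(c(64, 64), strength = 0)
  expect_true(all(f0 == 1))
  f <- generate_illumination_field(c(64, 64), strength = 0.4)
  expect_equal(max(f), 1)
  expect_true(all(f >= 0.6))
  expect_lt(f[1, 1], f[32, 32])             # corner below center
  # the farthest corner sits at 1 - strength (up to grid discretization of
  # the renormalized off-grid peak)
  expect_gte(min(f), 0.6)
  expect_lt(min(f), 0.602)
  fa <- generate_illumination_field(c(64, 64), 0.4, asymmetry = c(0.1, 0.1))
  peak <- which(fa == max(fa), arr.ind = TRUE)
  expect_true(peak[1, 1] > 34 && peak[1, 2] > 34)  # peak shifted off-center
  expect_error(generate_illumination_field(c(8, 8), strength = 1),
               "strength")
})

test_that("rendered scenes are deterministic and conserve cells", {
  p <- scene_params(n_frames = 4, n_cells = 6, seed = 11)
  a <- render_timelapse(p)
  b <- render_timelapse(p)
  expect_identical(a$frames, b$frames)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_equal(nrow(a$ground_truth$cells), 6)
  expect_equal(sum(a$ground_truth$tracks$frame == 1), 6)
  expect_true(all(unlist(a$frames) >= 0 & unlist(a$frames) <= 1))
})

test_that("trivial generator limits hold", {
  p0 <- scene_params(n_frames = 4, late_s_fraction = 0, seed = 2)
  expect_equal(nrow(render_timelapse(p0)$ground_truth$foci), 0)
  # empty scene with no bleaching: background constant over frames
  pb <- scene_params(n_cells = 0, n_frames = 5, noise_sd = 0,
                     bleach_halflife = Inf, vignette_strength = 0, seed = 1)
  fr <- render_timelapse(pb)$frames
  expect_true(all(vapply(fr, function(f) all(f == fr[[1]]), TRUE)))
  expect_equal(fr[[1]][1, 1], pb$background_level)
  # with bleaching the background halves after one half-life
  ph <- scene_params(n_cells = 0, n_frames = 5, noise_sd = 0,
                     bleach_halflife = 2, vignette_strength = 0, seed = 1)
  frh <- render_timelapse(ph)$frames
  expect_equal(frh[[3]][1, 1], frh[[1]][1, 1] / 2)
  expect_error(render_timelapse(scene_params(n_cells = 500, seed = 1)),
               "packing")
})

test_that("focus counts are Poisson with the requested rate", {
  # many body-positive cells in ground-truth-only mode; mean within 3 SE
  p <- scene_params(n_cells = 500, n_frames = 3, late_s_fraction = 1,
                    foci_rate_lambda = 3, dead_cell_fraction = 0,
                    micronucleus_fraction = 0, seed = 13)
  gt <- render_timelapse(p, render = FALSE)$ground_truth
  counts <- gt$cells$n_foci[gt$cells$positive]
  expect_gt(length(counts), 450)
  se <- sqrt(3 / length(counts))
  expect_lt(abs(mean(counts) - 3), 3 * se)
})

test_that("focus centroids lie inside the half-max nucleus mask", {
  p <- scene_params(n_frames = 6, late_s_fraction = 1, seed = 5)
  sc <- render_timelapse(p, render = FALSE)
  gt <- sc$ground_truth
  for (k in seq_len(nrow(gt$foci))) {
    f <- gt$foci[k, ]
    cell <- gt$cells[gt$cells$cell == f$cell, ]
    tr <- gt$tracks[gt$tracks$cell == f$cell & gt$tracks$frame == f$frame, ]
    dy <- f$y - tr$y; dx <- f$x - tr$x
    th <- cell$theta
    u <- dy * cos(th) + dx * sin(th); v <- -dy * sin(th) + dx * cos(th)
    expect_lte((u / cell$ry)^2 + (v / cell$rx)^2, 1)
  }
})

test_that("doubling focus amplitude doubles the peak above local background", {
  base <- list(n_cells = 1, n_frames = 1, late_s_fraction = 1, foci_count = 1,
               noise_sd = 0, vignette_strength = 0, dead_cell_fraction = 0,
               micronucleus_fraction = 0, seed = 21)
  f0 <- render_timelapse(do.call(scene_params, c(base, focus_amplitude = 0)))$frames[[1]]
  f1 <- render_timelapse(do.call(scene_params, c(base, focus_amplitude = 0.05)))$frames[[1]]
  f2 <- render_timelapse(do.call(scene_params, c(base, focus_amplitude = 0.10)))$frames[[1]]
  # the focus term isolated against the same nucleus/background rendering
  expect_equal(max(f2 - f0), 2 * max(f1 - f0), tolerance = 1e-6)
})

test_that("generate_plate validates effects and is deterministic", {
  layout <- make_screen_layout(n_library = 2, n_neg = 2, n_pold1 = 0, n_dek = 0)
  base <- scene_params(n_cells = 30, n_frames = 6)
  expect_error(generate_plate(layout, base, c(siXXX = 2), 2, seed = 1,
                              render = FALSE), "absent from layout")
  a <- generate_plate(layout, base, c(si001 = 3), 2, seed = 4, render = FALSE)
  b <- generate_plate(layout, base, c(si001 = 3), 2, seed = 4, render = FALSE)
  expect_identical(a$positions, b$positions)
  # multiplier 3 scales the ground-truth mean focus count of that siRNA
  mean_foci <- function(pl, s) {
    v <- unlist(lapply(pl$positions, function(p)
      if (p$sirna == s) p$scene$ground_truth$cells$n_foci[
        p$scene$ground_truth$cells$positive] else NULL))
    mean(v)
  }
  big <- generate_plate(layout, scene_params(n_cells = 150, n_frames = 3),
                        c(si001 = 3), 4, seed = 9, render = FALSE)
  ratio <- mean_foci(big, "si001") / mean_foci(big, "sNEG1")
  expect_gt(ratio, 2.5); expect_lt(ratio, 3.5)
})

test_that("simulated FRAP curves follow the recovery model", {
  cu <- simulate_frap_curve(tau = 10, plateau = 0.8, noise_sd = 0)
  expect_true(all(cu$intensity[cu$time < 0] == 1))
  i_tau <- which(cu$time == 10)
  expect_equal(cu$intensity[i_tau], 0.8 * (1 - exp(-1)))
  expect_equal(cu$intensity[length(cu$intensity)], 0.8, tolerance = 1e-4)
  expect_error(simulate_frap_curve(tau = -1), "tau")
  # noisy curves are deterministic per seed
  n1 <- simulate_frap_curve(10, 0.8, noise_sd = 0.02, seed = 3)
  n2 <- simulate_frap_curve(10, 0.8, noise_sd = 0.02, seed = 3)
  expect_identical(n1, n2)
})

test_that("ground truth CSV export uses 0-based coordinates", {
  p <- scene_params(n_cells = 3, n_frames = 2, seed = 8)
  sc <- render_timelapse(p, render = FALSE)
  path <- tempfile(fileext = ".csv")
  write_ground_truth(sc$ground_truth, path)
  d <- read.csv(path)
  expect_named(d, c("cell_id", "frame", "x", "y", "class", "n_foci"))
  expect_equal(min(d$frame), 0)
  expect_equal(d$y[1], sc$ground_truth$tracks$y[1] - 1)
})
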