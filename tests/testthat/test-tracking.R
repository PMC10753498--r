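test_that("link_frames matches identical objects to themselves", {
  lab <- disks_matrix(c(40, 40), rbind(c(10, 10), c(30, 28)), 5)
  objs <- objects_from_labels(lab)
  m <- link_frames(objs, objs)
  expect_equal(nrow(m), 2)
  expect_equal(m$prev, m$curr)
  expect_true(all(m$overlap == objs$area[match(m$prev, objs$label)]))
})

test_that("the 15 px gate and the overlap requirement both apply", {
  a <- objects_from_labels(disks_matrix(c(60, 60), rbind(c(20, 20)), 5))
  # displaced by 20 px: no overlap, outside the gate
  b <- objects_from_labels(disks_matrix(c(60, 60), rbind(c(20, 40)), 5))
  expect_equal(nrow(link_frames(a, b)), 0)
  # displaced by 14 px: inside the gate but disks of radius 5 do not overlap
  c_ <- objects_from_labels(disks_matrix(c(60, 60), rbind(c(20, 34)), 5))
  expect_equal(nrow(link_frames(a, c_)), 0)
  # displaced by 6 px: overlapping and inside the gate
  d <- objects_from_labels(disks_matrix(c(60, 60), rbind(c(20, 26)), 5))
  expect_equal(nrow(link_frames(a, d)), 1)
})

test_that("greedy assignment maximizes overlap on drift-like cases", {
  # two near-swapping objects with unequal overlaps (the spec's scenario)
  prev <- objects_from_labels(disks_matrix(c(60, 60), rbind(c(20, 20), c(20, 32)), 6))
  curr <- objects_from_labels(disks_matrix(c(60, 60), rbind(c(20, 23), c(20, 35)), 6))
  m <- link_frames(prev, curr)
  cand <- fociscreen:::link_candidates(prev, curr, 15)
  expect_equal(sum(m$overlap), oracle_best_assignment(cand))
  expect_equal(m$curr[m$prev == 1], 1)
  # random small constellations: greedy equals the exhaustive optimum when
  # objects drift less than their radius (the tracker's operating regime)
  set.seed(10)
  for (rep in 1:8) {
    n <- sample(3:5, 1)
    c0 <- separated_centers(n, 12, 68, 13)
    c1 <- c0 + matrix(rnorm(2 * n, 0, 2.5), n)
    prev <- objects_from_labels(disks_matrix(c(80, 80), c0, 5))
    curr <- objects_from_labels(disks_matrix(c(80, 80), c1, 5))
    m <- link_frames(prev, curr)
    cand <- fociscreen:::link_candidates(prev, curr, 15)
    expect_equal(sum(m$overlap), oracle_best_assignment(cand))
    expect_true(!anyDuplicated(m$prev) && !anyDuplicated(m$curr))
  }
  # adversarial overlaps: greedy achieves at least half the optimum
  for (rep in 1:8) {
    k <- sample(6:9, 1)
    cand <- data.frame(prev = sample(1:3, k, TRUE), curr = sample(1:3, k, TRUE),
                       overlap = sample(1:50, k), distance = runif(k, 0, 10))
    cand <- cand[!duplicated(cand[, c("prev", "curr")]), ]
    got <- fociscreen:::greedy_assign(cand)
    expect_gte(sum(got$overlap), oracle_best_assignment(cand) / 2)
  }
})

test_that("build_tracks produces consecutive single-identity tracks", {
  lab <- disks_matrix(c(40, 40), rbind(c(18, 18)), 6)
  objs <- objects_from_labels(lab)
  tr <- build_tracks(rep(list(objs), 5))
  expect_length(tr, 1)
  expect_equal(tr[[1]]$observations$frame, 1:5)
  expect_equal(tr[[1]]$counts, rep(0L, 5))
  # removing the nucleus at frame 3 splits the track
  frames <- rep(list(objs), 5); frames[[3]] <- objs[0, ]
  tr2 <- build_tracks(frames)
  expect_length(tr2, 2)
  expect_equal(tr2[[1]]$observations$frame, 1:2)
  expect_equal(tr2[[2]]$observations$frame, 4:5)
  # observation conservation
  expect_equal(sum(vapply(tr2, function(t) nrow(t$observations), 0)), 4)
})

test_that("focus counts attach to the owning track", {
  lab <- disks_matrix(c(40, 40), rbind(c(18, 18)), 6)
  objs <- objects_from_labels(lab)
  foci <- list(
    data.frame(nucleus = 1, row = 18, col = 18),
    data.frame(nucleus = integer(0), row = numeric(0), col = numeric(0)),
    data.frame(nucleus = c(1, 1), row = c(17, 19), col = c(18, 18))
  )
  tr <- build_tracks(rep(list(objs), 3), foci)
  expect_equal(tr[[1]]$counts, c(1L, 0L, 2L))
})

test_that("ground-truth cells are recovered as long single tracks", {
  # permissive viability thresholds isolate the tracker (the calibrated
  # filter removes ~1% of normal objects per frame by design, which breaks
  # tracks for reasons unrelated to linking)
  cfg <- run_config("primary",
                    viability_thresholds = c(sd_intensity = Inf,
                                             q75_intensity = Inf, area = -Inf))
  recovered <- total <- 0
  for (seed in c(77, 78)) {
    p <- scene_params(image_shape = c(320L, 320L), n_cells = 6, n_frames = 10,
                      dead_cell_fraction = 0, micronucleus_fraction = 0,
                      late_s_fraction = 0, seed = seed)
    sc <- render_timelapse(p)
    res <- analyze_position(sc$frames, sc$field, cfg, p$frame_interval)
    lens <- vapply(res$tracks, function(t) nrow(t$observations), 0)
    recovered <- recovered + sum(lens >= 9)
    total <- total + p$n_cells
  }
  # at least 95% of cells yield one track spanning >= 90% of frames
  expect_gte(recovered, ceiling(0.95 * total))
})
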