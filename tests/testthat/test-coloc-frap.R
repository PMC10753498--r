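test_that("Manders M1 follows its definition exactly", {
  ch1 <- matrix(c(1, 3, 2, 4), 2)             # [[1,2],[3,4]]
  expect_equal(manders_m1(ch1, matrix(1, 2, 2)), 1)
  expect_equal(manders_m1(ch1, matrix(0, 2, 2)), 0)
  ch2 <- matrix(c(0, 0, 5, 5), 2)             # [[0,5],[0,5]]
  expect_equal(manders_m1(ch1, ch2), 0.6)
  expect_warning(m <- manders_m1(matrix(0, 2, 2), ch2), "zero total")
  expect_true(is.na(m))
  # ROI restriction and threshold gate
  roi <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(manders_m1(ch1, matrix(1, 2, 2), roi = roi), 1)
  expect_equal(manders_m1(ch1, ch2, ch2_threshold = 5), 0)
})

test_that("Manders M1 matches a per-pixel loop oracle on random images", {
  set.seed(8)
  for (rep in 1:15) {
    ch1 <- matrix(runif(64), 8)
    ch2 <- matrix(sample(c(0, runif(1))), 8, 8) * matrix(runif(64) > 0.5, 8)
    thr <- sample(c(0, 0.1), 1)
    expect_identical(manders_m1(ch1, ch2, ch2_threshold = thr),
                     oracle_manders(ch1, ch2, thr))
  }
})

test_that("object colocalization uses the centroid-in-mask rule", {
  A <- disks_matrix(c(50, 50), rbind(c(10, 10), c(30, 30)), 3)
  r <- object_coloc_fraction(A, A)
  expect_equal(r$fraction_ab, 1); expect_equal(r$fraction_ba, 1)
  B <- disks_matrix(c(50, 50), rbind(c(10, 40)), 3)
  expect_equal(object_coloc_fraction(A, B)$fraction_ab, 0)
  # 10 A-objects, 7 planted inside B coverage
  centers <- cbind(seq(5, 95, by = 10), 30)
  A10 <- disks_matrix(c(100, 60), centers, 2)
  B7 <- disks_matrix(c(100, 60), centers[1:7, ], 4)
  r2 <- object_coloc_fraction(A10, B7)
  expect_equal(r2$fraction_ab, 0.7)
  expect_equal(r2$nA, 10); expect_equal(r2$nA_coloc, 7)
  small_b <- disks_matrix(c(5, 5), rbind(c(3, 3)), 1)
  expect_warning(r3 <- object_coloc_fraction(matrix(0L, 5, 5), small_b),
                 "no A objects")
  expect_true(is.na(r3$fraction_ab))
})

test_that("PLA positivity applies the micrometer radius", {
  bodies <- rbind(c(10, 10), c(40, 40))
  expect_equal(pla_positive_fraction(bodies, bodies, pixel_size = 0.1), 1)
  expect_equal(pla_positive_fraction(bodies, bodies[0, , drop = FALSE],
                                     pixel_size = 0.1), 0)
  # 10 px at 0.1 um/px is 1.0 um <= 1.5 um: positive
  expect_equal(pla_positive_fraction(rbind(c(0, 0)), rbind(c(10, 0)),
                                     pixel_size = 0.1), 1)
  # but 16 px (1.6 um) is not
  expect_equal(pla_positive_fraction(rbind(c(0, 0)), rbind(c(16, 0)),
                                     pixel_size = 0.1), 0)
  # monotone in the radius
  set.seed(2)
  b <- matrix(runif(20, 0, 50), 10); pu <- matrix(runif(10, 0, 50), 5)
  f <- vapply(c(0.5, 1, 1.5, 3, 10), function(r)
    pla_positive_fraction(b, pu, radius_um = r, pixel_size = 0.2), 0)
  expect_true(all(diff(f) >= 0))
  expect_warning(pla_positive_fraction(b[0, , drop = FALSE], pu, pixel_size = 1),
                 "no bodies")
})

test_that("line profiles interpolate bilinearly and normalize as asked", {
  cst <- matrix(4, 10, 10)
  pr <- line_profile(cst, c(1, 1), c(10, 10), n_samples = 7, normalize = "max1")
  expect_true(all(pr$intensity == 1))
  ramp <- matrix(rep(1:10, each = 10), 10)    # increases along columns
  pr2 <- line_profile(ramp, c(5, 1), c(5, 10), n_samples = 10,
                      normalize = "minmax")
  expect_equal(pr2$intensity, seq(0, 1, length.out = 10))
  sq <- matrix(c(0, 2, 2, 4), 2)              # [[0,2],[2,4]]
  pr3 <- line_profile(sq, c(1, 1), c(2, 2), n_samples = 3)
  expect_equal(pr3$intensity[2], 2)           # bilinear midpoint
  expect_error(line_profile(sq, c(1, 1), c(1, 1), 5), "zero-length")
  expect_error(line_profile(sq, c(0, 1), c(2, 2), 5), "outside")
  expect_error(line_profile(cst, c(1, 1), c(10, 10), normalize = "minmax"),
               "constant")
})

test_that("FRAP normalization is idempotent and affine-invariant", {
  cu <- simulate_frap_curve(10, 0.8, noise_sd = 0.01, seed = 6)
  n1 <- normalize_frap(cu)
  expect_equal(normalize_frap(n1)$intensity, n1$intensity)
  aff <- frap_curve(cu$time, 3.2 * cu$intensity + 0.7, cu$bleach_index)
  expect_equal(normalize_frap(aff)$intensity, n1$intensity)
  expect_equal(n1$intensity[n1$bleach_index], 0)   # first post-bleach pins 0
  flat <- frap_curve(0:9, rep(1, 10), bleach_index = 5)
  expect_error(normalize_frap(flat), "flat")
})

test_that("exponential FRAP fitting recovers tau", {
  f <- fit_frap(normalize_frap(simulate_frap_curve(10, 0.8, noise_sd = 0)))
  expect_equal(f$tau, 10, tolerance = 1e-3)
  expect_equal(f$plateau, 0.8, tolerance = 1e-3)
  expect_equal(f$half_time, f$tau * log(2))
  expect_lt(f$rms, 1e-6)
  # time rescaling doubles tau
  cu <- simulate_frap_curve(10, 0.8, noise_sd = 0)
  cu2 <- frap_curve(cu$time * 2, cu$intensity)
  expect_equal(fit_frap(normalize_frap(cu2))$tau, 20, tolerance = 1e-3)
  # a modest noisy batch is unbiased (full 200-curve case in acceptance)
  curves <- lapply(1:40, function(i)
    simulate_frap_curve(10, 0.8, noise_sd = 0.02, seed = i))
  b <- fit_frap_batch(curves)
  expect_lt(abs(b$tau_mean - 10) / 10, 0.05)
  expect_error(fit_frap(frap_curve(0:3, c(1, 0, 0.3, 0.5), 2)), ">= 5")
})
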