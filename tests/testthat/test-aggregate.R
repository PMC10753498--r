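test_that("close_gaps fills exactly one-frame interior gaps", {
  expect_equal(close_gaps(c(2, 1, 3)), c(2, 1, 3))
  expect_equal(close_gaps(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(close_gaps(c(2, 0, 3)), c(2, 2, 3))
  expect_equal(close_gaps(c(2, 0, 3), fill = "next"), c(2, 3, 3))
  expect_equal(close_gaps(c(2, 0, 0, 3)), c(2, 0, 0, 3))
  expect_equal(close_gaps(c(0, 2, 0)), c(0, 2, 0))  # boundary zeros untouched
})

test_that("close_gaps positivity equals dilate-then-erode closing", {
  set.seed(4)
  for (rep in 1:40) {
    counts <- sample(0:3, sample(1:12, 1), replace = TRUE,
                     prob = c(0.5, 0.2, 0.2, 0.1))
    got <- close_gaps(counts)
    expect_equal(as.integer(got > 0), oracle_close_positivity(as.integer(counts > 0)),
                 info = paste(counts, collapse = ","))
    # never removes positives; idempotent; original counts unchanged
    expect_true(all(got[counts > 0] == counts[counts > 0]))
    expect_gte(sum(got > 0), sum(counts > 0))
    expect_equal(close_gaps(got), got)
  }
})

test_that("longest_run picks the longest, earliest positive run", {
  expect_null(longest_run(c(0, 0, 0)))
  expect_equal(longest_run(c(1, 1, 0, 1, 1, 1)), c(4, 6))
  expect_equal(longest_run(c(1, 1, 0, 1, 1)), c(1, 2))   # tie: earliest
  expect_equal(longest_run(c(0, 5, 0)), c(2, 2))
})

test_that("summarize_track applies gap closing, longest run and persistence", {
  tr <- function(counts) structure(
    list(track_id = 1L,
         observations = data.frame(frame = seq_along(counts)),
         counts = counts), class = "focus_track")
  s <- summarize_track(tr(c(0, 3, 0)), frame_interval = 12)
  expect_equal(s$run_length, 0)
  expect_equal(s$mean_db_count, 0)
  s2 <- summarize_track(tr(c(2, 0, 3)), frame_interval = 12)
  expect_equal(c(s2$run_start, s2$run_end), c(1, 3))
  expect_equal(s2$mean_db_count, 7 / 3)
  expect_equal(s2$lifetime_min, 36)
  # zero-padding around the run leaves the readout unchanged
  s3 <- summarize_track(tr(c(0, 0, 2, 0, 3, 0, 0)), frame_interval = 12)
  expect_equal(s3$mean_db_count, s2$mean_db_count)
  expect_equal(s3$run_length, s2$run_length)
})

test_that("growth slope is the OLS slope of counts vs frame", {
  expect_equal(growth_slope(c(5, 5, 5, 5)), 0)
  expect_equal(growth_slope(c(10, 12, 14, 16)), 2)
  expect_equal(growth_slope(rev(c(10, 12, 14, 16))), -2)
  expect_warning(s <- growth_slope(7), "single frame")
  expect_true(is.na(s))
})

test_that("position QC combines all enabled rules", {
  ok <- list(integrated_intensity = 50, mean_cell_count = 20,
             growth_slope = 0.1, plls = c(-2, -2.1), filtered_ratio = 0.9)
  expect_true(qc_position(ok, qc_rules())$pass)
  bad_growth <- ok; bad_growth$growth_slope <- -0.5
  r <- qc_position(bad_growth, qc_rules())
  expect_false(r$pass); expect_false(r$checks[["growth"]])
  blank <- ok; blank$integrated_intensity <- 0
  expect_false(qc_position(blank, qc_rules(min_integrated_intensity = 1))$pass)
  bad_plls <- ok; bad_plls$plls <- c(-2, -5)
  expect_false(qc_position(bad_plls, qc_rules(plls_range = c(-3, 0)))$pass)
  # secondary-only rule requires the ratio stat
  r2 <- qc_position(ok, qc_rules(min_filtered_ratio = 0.95))
  expect_false(r2$pass)
  no_ratio <- ok; no_ratio$filtered_ratio <- NULL
  expect_error(qc_position(no_ratio, qc_rules(min_filtered_ratio = 0.5)),
               "filtered_ratio")
})

test_that("a constructed shrinking position fails the growth rule end-to-end", {
  p <- scene_params(n_cells = 6, n_frames = 6, late_s_fraction = 0,
                    dead_cell_fraction = 0, micronucleus_fraction = 0,
                    seed = 55)
  sc <- render_timelapse(p)
  # delete cells over time by blanking their pixels
  gt <- sc$ground_truth$tracks
  frames <- sc$frames
  for (f in 4:6) {
    kill <- gt[gt$frame == f & gt$cell <= (f - 3) * 2, ]
    for (k in seq_len(nrow(kill))) {
      rr <- pmax(1, round(kill$y[k]) - 30):pmin(256, round(kill$y[k]) + 30)
      cc <- pmax(1, round(kill$x[k]) - 30):pmin(256, round(kill$x[k]) + 30)
      frames[[f]][rr, cc] <- 0.05
    }
  }
  res <- analyze_position(frames, sc$field, run_config("primary"), 10)
  expect_lt(res$stats$growth_slope, 0)
  expect_false(res$qc$checks[["growth"]])
})
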