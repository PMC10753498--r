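# Track-level aggregation: gap closing of focus-count sequences, longest
# positive run, the mean-bodies-per-cell readout, and position-level QC.

#' Close single-frame gaps in a focus-count sequence
#'
#' The positivity pattern after filling equals the binary morphological
#' closing (structuring element of length 3) of the input's positivity
#' pattern: isolated interior zeros flanked by positive frames become
#' positive; longer gaps and boundary zeros are untouched. Filled frames
#' receive the count of the adjacent originally positive frame (`fill =
#' "previous"` takes the left neighbor, `"next"` the right). Originally
#' positive counts are never changed.
#'
#' @param counts Non-negative integer vector.
#' @param fill `"previous"` or `"next"`.
#' @return Integer vector of the same length.
#' @export
close_gaps <- function(counts, fill = c("previous", "next")) {
  fill <- match.arg(fill)
  stopifnot(all(counts >= 0))
  n <- length(counts)
  if (n < 3) return(counts)
  out <- counts
  gap <- which(counts[2:(n - 1)] == 0 & counts[1:(n - 2)] > 0 &
               counts[3:n] > 0) + 1L
  if (length(gap))
    out[gap] <- if (fill == "previous") counts[gap - 1L] else counts[gap + 1L]
  out
}

#' Longest run of positive counts
#'
#' @param counts Gap-closed count vector.
#' @return `c(start, end)` (1-based, inclusive) of the longest strictly
#'   positive run, earliest on ties; `NULL` if no positive entry.
#' @export
longest_run <- function(counts) {
  r <- rle(counts > 0)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- which(r$values)
  best <- pos[which.max(r$lengths[pos])]  # which.max takes the earliest tie
  c(starts[best], ends[best])
}

#' Summarize a track's focus-count time series
#'
#' Applies [close_gaps()] then [longest_run()]; runs shorter than
#' `min_persistence` frames are discarded (bodies must persist for at least
#' two consecutive frames by default). The main readout `mean_db_count` is
#' the mean count within the retained run; counts outside it are treated as
#' removed.
#'
#' @param track A `focus_track` from [build_tracks()] (or any list with
#'   `track_id`, `observations$frame`, `counts`).
#' @param frame_interval Minutes per frame, for the body-lifetime field.
#' @param min_persistence Minimum run length in frames.
#' @param fill Gap-fill policy, see [close_gaps()].
#' @return One-row data.frame: `track_id, track_length, run_start, run_end,
#'   run_length, mean_db_count, lifetime_min`.
#' @export
summarize_track <- function(track, frame_interval = 10, min_persistence = 2,
                            fill = "previous") {
  counts <- close_gaps(track$counts, fill)
  run <- longest_run(counts)
  frames <- track$observations$frame
  if (is.null(run) || (run[2] - run[1] + 1) < min_persistence) {
    return(data.frame(track_id = track$track_id, track_length = length(counts),
                      run_start = NA_integer_, run_end = NA_integer_,
                      run_length = 0L, mean_db_count = 0,
                      lifetime_min = 0))
  }
  len <- run[2] - run[1] + 1L
  data.frame(track_id = track$track_id, track_length = length(counts),
             run_start = frames[run[1]], run_end = frames[run[2]],
             run_length = len,
             mean_db_count = mean(counts[run[1]:run[2]]),
             lifetime_min = len * frame_interval)
}

#' Least-squares growth slope of per-frame cell counts
#'
#' @param cell_counts Integer vector of cells per frame.
#' @return OLS slope (cells/frame); `NA` with a warning for fewer than 2
#'   frames.
#' @export
growth_slope <- function(cell_counts) {
  n <- length(cell_counts)
  if (n < 2) {
    warning("growth slope undefined for a single frame")
    return(NA_real_)
  }
  x <- seq_len(n)
  sum((x - mean(x)) * (cell_counts - mean(cell_counts))) / sum((x - mean(x))^2)
}

#' Position-level quality-control rules
#'
#' @param min_integrated_intensity Minimum mean (over frames) total nuclear
#'   intensity.
#' @param min_cell_count Minimum mean cells per frame.
#' @param min_growth_slope Minimum growth slope (default 0: negative growth
#'   fails).
#' @param plls_range Allowed `[lo, hi]` for every frame's power log-log
#'   slope.
#' @param min_filtered_ratio Secondary-screen rule: minimum ratio of kept to
#'   all identified nuclei (`NA` disables).
#' @return A `qc_rules` list.
#' @export
qc_rules <- function(min_integrated_intensity = 0,
                     min_cell_count = 1,
                     min_growth_slope = 0,
                     plls_range = c(-Inf, Inf),
                     min_filtered_ratio = NA) {
  r <- list(min_integrated_intensity = min_integrated_intensity,
            min_cell_count = min_cell_count,
            min_growth_slope = min_growth_slope,
            plls_range = plls_range,
            min_filtered_ratio = min_filtered_ratio)
  stopifnot(length(r$plls_range) == 2)
  class(r) <- "qc_rules"
  r
}

#' Position quality control
#'
#' @param stats List or one-row data.frame with `integrated_intensity`
#'   (mean over frames of summed nuclear intensity), `mean_cell_count`,
#'   `growth_slope`, `plls` (vector over frames), and optionally
#'   `filtered_ratio` (kept / identified nuclei).
#' @param rules A [qc_rules()].
#' @return List with `pass` and a named logical vector `checks`.
#' @export
qc_position <- function(stats, rules = qc_rules()) {
  checks <- c(
    intensity = stats$integrated_intensity >= rules$min_integrated_intensity,
    cell_count = stats$mean_cell_count >= rules$min_cell_count,
    growth = !is.na(stats$growth_slope) &&
      stats$growth_slope >= rules$min_growth_slope,
    plls = all(is.finite(stats$plls) & stats$plls >= rules$plls_range[1] &
                 stats$plls <= rules$plls_range[2])
  )
  if (!is.na(rules$min_filtered_ratio)) {
    if (is.null(stats$filtered_ratio))
      stop("filtered-ratio rule enabled but `filtered_ratio` missing")
    checks <- c(checks,
                filtered_ratio = stats$filtered_ratio >= rules$min_filtered_ratio)
  }
  list(pass = all(checks), checks = checks)
}
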