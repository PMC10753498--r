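# End-to-end orchestration: configuration, the per-position pipeline
# (preprocess -> nuclei -> foci -> tracking -> aggregate), screen scoring,
# CSV/JSON outputs, and the transfection design calculator.

#' Pipeline run configuration
#'
#' Bundles every tunable of the screen pipeline. `profile` selects the
#' primary or secondary parameter set for segmentation and focus detection.
#'
#' @param profile `"primary"` or `"secondary"`.
#' @param crop A [crop_spec()]; use `crop_spec(0, 0, 0, 0)` for synthetic
#'   scenes without residual corner vignetting.
#' @param background_fwhm,background_min_diameter Background-mask parameters.
#' @param max_distance Tracking centroid gate (px).
#' @param min_persistence Minimum body-run length (frames).
#' @param gap_fill Gap-fill policy (`"previous"` or `"next"`).
#' @param pseudocount Z-score log2 pseudocount.
#' @param up_threshold,down_threshold Hit-call thresholds.
#' @param qc A [qc_rules()].
#' @param segmentation,foci Optional profile overrides
#'   ([segmentation_profile()], [foci_profile()]).
#' @param viability_thresholds Optional named vector overriding the
#'   segmentation profile's filter thresholds.
#' @param seed Seed recorded in run metadata.
#' @return A `run_config` list.
#' @export
run_config <- function(profile = c("primary", "secondary"),
                       crop = crop_spec(0, 0, 0, 0),
                       background_fwhm = 6,
                       background_min_diameter = 15,
                       max_distance = 15,
                       min_persistence = 2,
                       gap_fill = "previous",
                       pseudocount = 1 / 64,
                       up_threshold = 3,
                       down_threshold = -2,
                       qc = qc_rules(),
                       segmentation = NULL,
                       foci = NULL,
                       viability_thresholds = NULL,
                       seed = 1L) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile, crop = crop,
    background_fwhm = background_fwhm,
    background_min_diameter = background_min_diameter,
    max_distance = max_distance, min_persistence = min_persistence,
    gap_fill = gap_fill, pseudocount = pseudocount,
    up_threshold = up_threshold, down_threshold = down_threshold,
    qc = qc,
    segmentation = segmentation %||% segmentation_profile(profile),
    foci = foci %||% foci_profile(profile),
    viability_thresholds = viability_thresholds,
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Analyze one time-lapse position
#'
#' Runs the full per-position pipeline: power log-log slope on the raw
#' frames, vignetting correction, margin crop, masked-median background
#' subtraction, nuclei segmentation and viability filtering, focus
#' detection, overlap tracking, and track summarization.
#'
#' @param frames List of raw frame matrices (a `timelapse`).
#' @param field Illumination reference field (same shape as the raw frames),
#'   or `NULL` to skip the correction.
#' @param config A [run_config()].
#' @param frame_interval Minutes per frame.
#' @return List: `summaries` (track summaries), `readout` (`x`),
#'   `qc` ([qc_position()] result), `stats` (per-frame diagnostics),
#'   `tracks`, `nuclei` (per frame), `foci` (per frame).
#' @export
analyze_position <- function(frames, field = NULL, config = run_config(),
                             frame_interval = 10) {
  n <- length(frames)
  plls <- vapply(frames, function(f)
    suppressWarnings(power_loglog_slope(f)), 0)
  nuclei <- vector("list", n); foci <- vector("list", n)
  n_all <- n_kept <- integer(n)
  intensity <- numeric(n); bg <- numeric(n)
  for (f in seq_len(n)) {
    img <- frames[[f]]
    if (!is.null(field)) img <- correct_vignetting(img, field)
    img <- crop_margins(img, config$crop)
    sb <- subtract_background(img, config$background_fwhm,
                              config$background_min_diameter)
    bg[f] <- sb$background_value
    objs <- segment_nuclei(sb$frame, config$segmentation)
    n_all[f] <- nrow(objs)
    flt <- filter_viable(objs, config$segmentation, config$viability_thresholds)
    n_kept[f] <- nrow(flt$kept)
    intensity[f] <- sum(flt$kept$integrated_intensity)
    nuclei[[f]] <- flt$kept
    foci[[f]] <- detect_foci(sb$frame, flt$kept, config$foci)
  }
  tracks <- build_tracks(nuclei, foci, config$max_distance)
  summaries <- if (length(tracks))
    do.call(rbind, lapply(tracks, summarize_track,
                          frame_interval = frame_interval,
                          min_persistence = config$min_persistence,
                          fill = config$gap_fill))
  else NULL
  stats <- list(
    integrated_intensity = mean(intensity),
    mean_cell_count = mean(n_kept),
    growth_slope = growth_slope(n_kept),
    plls = plls,
    filtered_ratio = if (sum(n_all) > 0) sum(n_kept) / sum(n_all) else NA_real_,
    background = bg
  )
  x <- if (is.null(summaries)) NA_real_ else
    suppressWarnings(position_readout(summaries))
  list(summaries = summaries, readout = x,
       qc = qc_position(stats, config$qc), stats = stats,
       tracks = tracks, nuclei = nuclei, foci = foci)
}

#' Run the screen pipeline on a plate dataset
#'
#' Analyzes every position of one or more [generate_plate()] datasets (or
#' equivalently structured lists of positions with `frames`), scores
#' replicate-wise Z-scores against sNEG1 positions, summarizes per siRNA and
#' calls hits. When `output_dir` is given, writes `positions.csv`,
#' `sirna.csv`, `hits.csv` and `run_metadata.json`.
#'
#' @param plates A `plate_dataset` or list of them (one per replicate).
#' @param config A [run_config()].
#' @param output_dir Optional output directory.
#' @param use_ground_truth If `TRUE`, skip pixel analysis and compute track
#'   summaries from the generator's ground truth (for score calibration at
#'   scales where full image analysis is not feasible; see vignette).
#' @return List: `positions` (per-position table with `x`, `z`, `qc_pass`),
#'   `sirna` (per-siRNA table), `hits`, `control_stats`.
#' @export
run_pipeline <- function(plates, config = run_config(), output_dir = NULL,
                         use_ground_truth = FALSE) {
  if (inherits(plates, "plate_dataset")) plates <- list(plates)
  rows <- list()
  for (plate in plates) {
    for (pos in plate$positions) {
      fi <- plate$base$frame_interval
      if (use_ground_truth) {
        summ <- ground_truth_summaries(pos$scene$ground_truth, fi,
                                       config$min_persistence)
        x <- if (is.null(summ)) NA_real_ else
          suppressWarnings(position_readout(summ))
        qc_pass <- TRUE
      } else {
        res <- analyze_position(pos$scene$frames, pos$scene$field, config, fi)
        x <- res$readout
        qc_pass <- res$qc$pass
      }
      rows[[length(rows) + 1]] <- data.frame(
        replicate = pos$replicate, well = pos$well, position = pos$position,
        sirna = pos$sirna, role = pos$role, x = x, qc_pass = qc_pass,
        stringsAsFactors = FALSE)
    }
  }
  positions <- do.call(rbind, rows)
  scored <- zscore_positions(positions, config$pseudocount)
  sirna <- summarize_sirna(scored[scored$role != "sNEG1", , drop = FALSE])
  hits <- call_hits(sirna, config$up_threshold, config$down_threshold)
  out <- list(positions = scored, sirna = sirna, hits = hits,
              control_stats = attr(scored, "control_stats"),
              all_positions = positions)
  if (!is.null(output_dir)) write_run_outputs(out, config, output_dir)
  out
}

write_run_outputs <- function(run, config, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(run$positions, file.path(output_dir, "positions.csv"),
            row.names = FALSE)
  sirna <- run$sirna
  sirna$hit <- run$hits$class
  write.csv(sirna, file.path(output_dir, "sirna.csv"), row.names = FALSE)
  write.csv(rbind(run$hits$up, run$hits$down),
            file.path(output_dir, "hits.csv"), row.names = FALSE)
  meta <- config
  meta$crop <- unclass(meta$crop); meta$qc <- unclass(meta$qc)
  meta$segmentation <- unclass(meta$segmentation)
  meta$foci <- unclass(meta$foci)
  jsonlite::write_json(meta, file.path(output_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(output_dir)
}

#' Final siRNA concentration of a reverse-transfection protocol
#'
#' `stock_conc * stock_vol / mix_vol / dilution_factor * dispensed_vol /
#' medium_vol`, rounded to `digits`. The primary screen's solid-phase
#' protocol (3000 nM stock, 5 ul into a 19 ul mix, 1:51 dilution, 50 ul
#' dispensed, 100 ul medium) gives 7.7 nM; the secondary liquid-phase
#' protocol (100 nM, 25 ul into 240 ul total, no further dilution) gives
#' 10.4 nM.
#'
#' @param stock_conc Stock concentration (nM).
#' @param stock_vol Stock volume pipetted into the mix (ul).
#' @param mix_vol Total mix volume (ul).
#' @param dilution_factor Subsequent dilution factor (1 = none).
#' @param dispensed_vol Volume of diluted mix dispensed per well (ul).
#' @param medium_vol Final medium volume per well (ul).
#' @param digits Rounding, `NULL` for no rounding.
#' @return Final concentration (nM).
#' @export
sirna_final_concentration <- function(stock_conc, stock_vol, mix_vol,
                                      dilution_factor = 1, dispensed_vol,
                                      medium_vol, digits = 1) {
  args <- c(stock_conc, stock_vol, mix_vol, dilution_factor, dispensed_vol,
            medium_vol)
  if (any(!is.finite(args)) || any(args <= 0))
    stop("all concentrations, volumes and factors must be positive")
  x <- stock_conc * stock_vol / mix_vol / dilution_factor *
    dispensed_vol / medium_vol
  if (is.null(digits)) x else round(x, digits)
}

#' Save a QC overlay image of one analyzed frame
#'
#' Renders the frame as grayscale with detected foci circled and kept nuclei
#' outlined, mirroring the screen's compressed overview images.
#'
#' @param frame Numeric matrix (preprocessed).
#' @param nuclei Kept nucleus table.
#' @param foci Focus table for the frame.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
save_overlay <- function(frame, nuclei, foci, path) {
  grDevices::png(path, width = ncol(frame), height = nrow(frame))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  rng <- range(frame)
  img <- if (diff(rng) > 0) (frame - rng[1]) / diff(rng) else frame * 0
  graphics::plot(NA, xlim = c(0.5, ncol(frame) + 0.5),
                 ylim = c(nrow(frame) + 0.5, 0.5), xaxs = "i", yaxs = "i",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(grDevices::as.raster(img), 0.5, nrow(frame) + 0.5,
                        ncol(frame) + 0.5, 0.5)
  if (!is.null(nuclei) && nrow(nuclei) > 0)
    graphics::symbols(nuclei$col, nuclei$row,
                      circles = nuclei$equivalent_diameter / 2,
                      inches = FALSE, add = TRUE, fg = "white")
  if (!is.null(foci) && nrow(foci) > 0)
    graphics::symbols(foci$col, foci$row,
                      circles = pmax(foci$equivalent_diameter, 2),
                      inches = FALSE, add = TRUE, fg = "red")
  invisible(path)
}
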