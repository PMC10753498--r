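# Plate layouts and plate-scale simulation.

PLATE_ROLES <- c("library", "sNEG1", "sPOLD1", "sDEK", "empty")

#' Construct and validate a plate layout
#'
#' @param wells A data.frame with columns `well`, `sirna`, `role` and
#'   optionally `gene`. Roles must be one of `library`, `sNEG1`, `sPOLD1`,
#'   `sDEK`, `empty`. Well names are normalized to letter + 2-digit form
#'   (`A1` becomes `A01`).
#' @param plate_id Identifier stored on the layout.
#' @return A `plate_layout` data.frame.
#' @export
plate_layout <- function(wells, plate_id = "plate1") {
  stopifnot(is.data.frame(wells), all(c("well", "sirna", "role") %in% names(wells)))
  wells$well <- normalize_well(wells$well)
  if (anyDuplicated(wells$well)) stop("duplicate well ids in layout")
  bad <- setdiff(unique(wells$role), PLATE_ROLES)
  if (length(bad))
    stop("unknown well role(s): ", paste(bad, collapse = ", "))
  if (sum(wells$role == "sNEG1") < 2)
    stop("layout needs >= 2 sNEG1 wells per plate for control statistics")
  if (!"gene" %in% names(wells)) wells$gene <- wells$sirna
  attr(wells, "plate_id") <- plate_id
  class(wells) <- c("plate_layout", "data.frame")
  wells
}

#' Normalize well names to letter + two digits
#'
#' @param well Character vector like `"A1"`, `"a01"`, `"H12"`.
#' @return Normalized well ids (`"A01"` form).
#' @export
normalize_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-P])0*([0-9]{1,2})$", well))
  bad <- vapply(m, length, 0L) != 3
  if (any(bad)) stop("malformed well id(s): ", paste(well[bad], collapse = ", "))
  vapply(m, function(g) sprintf("%s%02d", g[2], as.integer(g[3])), "")
}

#' A screening-plate layout in the primary-screen style
#'
#' Builds a layout with two wells per library siRNA, four negative-control
#' (sNEG1) wells, two positive-control (sPOLD1) wells, two transfection
#' control (sDEK) wells and optional empty wells, matching the primary
#' screen's plate design.
#'
#' @param n_library Number of distinct library siRNAs (each gets 2 wells).
#' @param n_neg,n_pold1,n_dek,n_empty Control/empty well counts.
#' @param plate_id Plate identifier.
#' @return A [plate_layout()].
#' @export
make_screen_layout <- function(n_library, n_neg = 4, n_pold1 = 2, n_dek = 2,
                               n_empty = 0, plate_id = "plate1") {
  sirnas <- sprintf("si%03d", seq_len(n_library))
  rows <- c(
    lapply(seq_len(n_neg), function(i) c("sNEG1", "sNEG1")),
    lapply(seq_len(n_pold1), function(i) c("sPOLD1", "sPOLD1")),
    lapply(seq_len(n_dek), function(i) c("sDEK", "sDEK")),
    lapply(rep(sirnas, each = 2), function(s) c(s, "library")),
    lapply(seq_len(n_empty), function(i) c("empty", "empty"))
  )
  n <- length(rows)
  if (n > 96) stop("layout exceeds 96 wells")
  wells <- paste0(rep(LETTERS[1:8], each = 12), sprintf("%02d", rep(1:12, 8)))[seq_len(n)]
  plate_layout(data.frame(
    well = wells,
    sirna = vapply(rows, `[`, "", 1),
    role = vapply(rows, `[`, "", 2),
    stringsAsFactors = FALSE
  ), plate_id = plate_id)
}

#' Generate a plate of synthetic positions with ground truth
#'
#' One time lapse + ground truth per (well, position). Per-siRNA `effects`
#' multiply the foci rate `lambda`; negative-control wells always use
#' multiplier 1. Deterministic given `seed`.
#'
#' @param layout A [plate_layout()].
#' @param base A [scene_params()] object used for every position.
#' @param effects Named numeric vector of foci-rate multipliers keyed by
#'   siRNA id; siRNAs not named get multiplier 1.
#' @param n_positions Fields of view per well.
#' @param seed Integer seed.
#' @param replicate Replicate id recorded on each position.
#' @param render Render pixels (`TRUE`) or ground truth only.
#' @return A `plate_dataset`: list with `layout`, `positions` (list of
#'   `well`, `position`, `replicate`, `sirna`, `role`, `scene`), `effects`.
#' @export
generate_plate <- function(layout, base, effects = numeric(0),
                           n_positions = 4, seed = 1L, replicate = 1L,
                           render = TRUE) {
  stopifnot(inherits(layout, "plate_layout"), inherits(base, "scene_params"))
  if (length(effects)) {
    unknown <- setdiff(names(effects), layout$sirna)
    if (length(unknown))
      stop("effect specified for siRNA(s) absent from layout: ",
           paste(unknown, collapse = ", "))
  }
  use <- layout[layout$role != "empty", , drop = FALSE]
  positions <- vector("list", nrow(use) * n_positions)
  k <- 0L
  for (w in seq_len(nrow(use))) {
    mult <- 1
    if (use$role[w] == "library" && use$sirna[w] %in% names(effects))
      mult <- effects[[use$sirna[w]]]
    p <- base
    p$foci_rate_lambda <- base$foci_rate_lambda * mult
    for (pos in seq_len(n_positions)) {
      k <- k + 1L
      # per-position seed, kept within 32-bit range
      p$seed <- as.integer((as.double(seed) * 10007 + as.double(replicate) * 977 +
                            w * 131 + pos) %% .Machine$integer.max)
      positions[[k]] <- list(
        well = use$well[w], position = pos, replicate = replicate,
        sirna = use$sirna[w], role = use$role[w],
        scene = render_timelapse(p, render = render)
      )
    }
  }
  structure(list(layout = layout, positions = positions, effects = effects,
                 base = base, n_positions = n_positions, seed = seed,
                 replicate = replicate),
            class = "plate_dataset")
}

#' Generate a replicated screen dataset
#'
#' @inheritParams generate_plate
#' @param n_replicates Number of biological replicates.
#' @return List of `plate_dataset`, one per replicate.
#' @export
generate_screen <- function(layout, base, effects = numeric(0),
                            n_positions = 4, n_replicates = 2, seed = 1L,
                            render = TRUE) {
  lapply(seq_len(n_replicates), function(r)
    generate_plate(layout, base, effects, n_positions,
                   seed = seed, replicate = r, render = render))
}

#' Per-cell ground-truth focus-count summaries for a plate position
#'
#' Feeds the generator's true per-frame focus counts of viable cells through
#' the same aggregation path the image pipeline uses (gap closing, longest
#' run, persistence gate), yielding track summaries without pixel detection.
#' Used to calibrate and test the scoring stage at scales where rendering
#' and segmenting hundreds of positions is not feasible.
#'
#' @param gt A `ground_truth` object.
#' @param frame_interval Minutes per frame.
#' @param min_persistence Minimum run length in frames.
#' @return A data.frame of track summaries (one row per viable cell).
#' @export
ground_truth_summaries <- function(gt, frame_interval = 10, min_persistence = 2) {
  cells <- gt$cells[gt$cells$class %in% c("normal", "micronucleated"), , drop = FALSE]
  if (nrow(cells) == 0) return(NULL)
  n_frames <- max(gt$tracks$frame)
  res <- vapply(seq_len(nrow(cells)), function(k) {
    counts <- integer(n_frames)
    if (isTRUE(cells$positive[k]) && cells$n_foci[k] > 0)
      counts[cells$start[k]:cells$end[k]] <- cells$n_foci[k]
    counts <- close_gaps(counts)
    run <- longest_run(counts)
    if (is.null(run) || (run[2] - run[1] + 1) < min_persistence)
      return(c(0, 0, NA, NA))
    len <- run[2] - run[1] + 1
    c(len, mean(counts[run[1]:run[2]]), run[1], run[2])
  }, numeric(4))
  data.frame(track_id = cells$cell, track_length = n_frames,
             run_start = as.integer(res[3, ]), run_end = as.integer(res[4, ]),
             run_length = as.integer(res[1, ]), mean_db_count = res[2, ],
             lifetime_min = res[1, ] * frame_interval)
}
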