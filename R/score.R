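# Screen scoring: per-position readout, replicate-wise log2 Z-scores
# against negative-control positions, per-siRNA means, ranks and hit calls.

#' Per-position readout: mean bodies per cell
#'
#' The mean over tracks of each track's `mean_db_count` (tracks that never
#' sustain a body run contribute 0).
#'
#' @param summaries Data.frame of track summaries ([summarize_track()] rows).
#' @return The readout `x`, or `NA` with a warning when there are no tracks.
#' @export
position_readout <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0) {
    warning("position has no tracks; readout undefined")
    return(NA_real_)
  }
  mean(summaries$mean_db_count)
}

#' Negative-control statistics for one replicate
#'
#' Mean and sample standard deviation of `log2(x + pseudocount)` over the
#' replicate's QC-passing sNEG1 positions.
#'
#' @param x Readouts of the replicate's sNEG1 positions.
#' @param pseudocount Added before the log2 (guards zero-body positions).
#' @return List `m`, `s`, `n`.
#' @export
control_stats <- function(x, pseudocount = 1 / 64) {
  x <- x[!is.na(x)]
  if (length(x) < 2)
    stop("need >= 2 QC-passing sNEG1 positions per replicate for scoring")
  lx <- log2(x + pseudocount)
  s <- sd(lx)
  if (!is.finite(s) || s == 0)
    stop("negative-control readouts are degenerate (sd = 0); replicate rejected")
  list(m = mean(lx), s = s, n = length(x))
}

#' Z-scores of position readouts against replicate controls
#'
#' `Z = (log2(x + pseudocount) - m) / s`, with `m`, `s` taken from the
#' position's own replicate's sNEG1 statistics. QC-failing positions and
#' positions from replicates without valid control statistics are excluded.
#'
#' @param positions Data.frame with at least `replicate`, `well`, `position`,
#'   `sirna`, `role`, `x`, `qc_pass`.
#' @param pseudocount Added before the log2.
#' @return The scored rows of `positions`, with columns `log2_x` and `z`
#'   added, plus an attribute `control_stats` (per-replicate list).
#' @export
zscore_positions <- function(positions, pseudocount = 1 / 64) {
  ok <- positions$qc_pass & !is.na(positions$x)
  scored <- positions[ok, , drop = FALSE]
  stats <- list()
  keep <- logical(nrow(scored))
  scored$log2_x <- log2(scored$x + pseudocount)
  scored$z <- NA_real_
  for (r in unique(scored$replicate)) {
    in_rep <- scored$replicate == r
    ctrl <- scored$x[in_rep & scored$role == "sNEG1"]
    st <- tryCatch(control_stats(ctrl, pseudocount), error = function(e) NULL)
    if (is.null(st)) {
      message("replicate ", r, " has no valid control statistics; excluded")
      next
    }
    stats[[as.character(r)]] <- st
    scored$z[in_rep] <- (scored$log2_x[in_rep] - st$m) / st$s
    keep[in_rep] <- TRUE
  }
  out <- scored[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "control_stats") <- stats
  out
}

#' Per-siRNA mean Z-scores, ranks and counts
#'
#' @param rows Scored positions from [zscore_positions()].
#' @return Data.frame sorted by decreasing mean Z: `sirna, role, mean_z,
#'   n_scores, rank`.
#' @export
summarize_sirna <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0)
    return(data.frame(sirna = character(0), role = character(0),
                      mean_z = numeric(0), n_scores = integer(0),
                      rank = integer(0)))
  agg <- aggregate(rows$z, by = list(sirna = rows$sirna, role = rows$role),
                   FUN = mean)
  cnt <- aggregate(rows$z, by = list(sirna = rows$sirna, role = rows$role),
                   FUN = length)
  out <- data.frame(sirna = agg$sirna, role = agg$role, mean_z = agg$x,
                    n_scores = cnt$x)
  out <- out[order(-out$mean_z, out$sirna), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Call screen hits from per-siRNA mean Z-scores
#'
#' Up hits have mean Z at or above `up_threshold`, down hits at or below
#' `down_threshold` (defaults 3 and -2). A gene-level rollup (any qualifying
#' siRNA) is included when a `gene` column is present.
#'
#' @param table Per-siRNA table from [summarize_sirna()].
#' @param up_threshold,down_threshold Z thresholds; `up > down` required.
#' @param library_only Restrict calls to `role == "library"` rows.
#' @return List with `up`, `down` (data.frames), `class` (vector aligned to
#'   `table` rows: `"up"`, `"down"`, `"none"`), and optional `genes_up`,
#'   `genes_down`.
#' @export
call_hits <- function(table, up_threshold = 3, down_threshold = -2,
                      library_only = TRUE) {
  stopifnot(up_threshold > down_threshold)
  eligible <- if (library_only && "role" %in% names(table))
    table$role == "library" else rep(TRUE, nrow(table))
  cls <- ifelse(eligible & table$mean_z >= up_threshold, "up",
         ifelse(eligible & table$mean_z <= down_threshold, "down", "none"))
  out <- list(up = table[cls == "up", , drop = FALSE],
              down = table[cls == "down", , drop = FALSE],
              class = cls)
  if ("gene" %in% names(table)) {
    out$genes_up <- unique(table$gene[cls == "up"])
    out$genes_down <- unique(table$gene[cls == "down"])
  }
  out
}
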