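# Overlap tracking of filtered nuclei across consecutive frames.

#' Link nucleus objects between two consecutive frames
#'
#' Candidate pairs share at least one pixel and have centroid distance at
#' most `max_distance`. Assignment is greedy one-to-one in decreasing shared
#' pixel count, ties broken by smaller centroid distance, then by smaller
#' (prev label, curr label).
#'
#' @param prev,curr Nucleus tables carrying `label`, `row`, `col`, `pixels`.
#' @param max_distance Centroid gate in pixels.
#' @return Data.frame `prev, curr, overlap, distance`, one row per match.
#' @export
link_frames <- function(prev, curr, max_distance = 15) {
  greedy_assign(link_candidates(prev, curr, max_distance))
}

# candidate pairs: centroid distance within the gate AND > 0 shared pixels
link_candidates <- function(prev, curr, max_distance) {
  empty <- data.frame(prev = integer(0), curr = integer(0),
                      overlap = integer(0), distance = numeric(0))
  if (is.null(prev) || is.null(curr) || nrow(prev) == 0 || nrow(curr) == 0)
    return(empty)
  cand <- list()
  for (i in seq_len(nrow(prev))) {
    d <- sqrt((prev$row[i] - curr$row)^2 + (prev$col[i] - curr$col)^2)
    for (j in which(d <= max_distance)) {
      ov <- length(intersect(prev$pixels[[i]], curr$pixels[[j]]))
      if (ov > 0)
        cand[[length(cand) + 1]] <- data.frame(
          prev = prev$label[i], curr = curr$label[j],
          overlap = ov, distance = d[j])
    }
  }
  if (!length(cand)) return(empty)
  do.call(rbind, cand)
}

# greedy one-to-one assignment in decreasing overlap; ties by smaller
# centroid distance, then smaller (prev, curr) labels
greedy_assign <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(-cand$overlap, cand$distance, cand$prev, cand$curr), ,
               drop = FALSE]
  used_p <- used_c <- integer(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand$prev[k] %in% used_p || cand$curr[k] %in% used_c) next
    keep[k] <- TRUE
    used_p <- c(used_p, cand$prev[k]); used_c <- c(used_c, cand$curr[k])
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build tracks over a time-ordered list of segmented frames
#'
#' Links consecutive frames with [link_frames()]; unmatched current objects
#' start new tracks and unmatched previous objects terminate, so every track
#' covers strictly consecutive frames. Per-frame focus counts (number of
#' foci assigned to the track's nucleus in that frame) are attached.
#'
#' @param frames List (by frame) of nucleus tables.
#' @param foci Optional list (by frame) of focus tables from [detect_foci()].
#' @param max_distance Centroid gate in pixels.
#' @return List of `focus_track` objects: `track_id`, `observations`
#'   (frame, label, row, col, area, intensity features), `counts` (integer
#'   per-frame focus counts).
#' @export
build_tracks <- function(frames, foci = NULL, max_distance = 15) {
  n <- length(frames)
  tracks <- list()
  active <- list()  # label -> track index, for the previous frame
  next_id <- 0L
  feat_cols <- c("label", "row", "col", "area", "mean_intensity",
                 "integrated_intensity")
  obs_row <- function(objs, j, f) {
    cbind(data.frame(frame = f), objs[j, intersect(feat_cols, names(objs)),
                                       drop = FALSE])
  }
  focus_count <- function(f, label) {
    if (is.null(foci) || length(foci) < f || is.null(foci[[f]])) return(0L)
    sum(foci[[f]]$nucleus == label)
  }
  for (f in seq_len(n)) {
    objs <- frames[[f]]
    new_active <- list()
    if (f > 1 && !is.null(objs) && nrow(objs) > 0 && length(active) > 0) {
      links <- link_frames(frames[[f - 1]], objs, max_distance)
    } else {
      links <- data.frame(prev = integer(0), curr = integer(0))
    }
    if (!is.null(objs) && nrow(objs) > 0) {
      for (j in seq_len(nrow(objs))) {
        lab <- objs$label[j]
        m <- links$prev[match(lab, links$curr)]
        ti <- if (!is.na(m)) active[[as.character(m)]] else NULL
        if (is.null(ti)) {
          next_id <- next_id + 1L
          ti <- next_id
          tracks[[ti]] <- list(track_id = ti,
                               observations = obs_row(objs, j, f),
                               counts = integer(0))
        } else {
          tracks[[ti]]$observations <- rbind(tracks[[ti]]$observations,
                                             obs_row(objs, j, f))
        }
        tracks[[ti]]$counts <- c(tracks[[ti]]$counts, focus_count(f, lab))
        new_active[[as.character(lab)]] <- ti
      }
    }
    active <- new_active
  }
  lapply(tracks, function(t) { class(t) <- "focus_track"; t })
}
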