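#' Per-condition tracking configuration
#'
#' @param cycle_times frame cycle times (s) the rows refer to.
#' @param tracking_radius maximum frame-to-frame displacement (pixels) for
#'   linking two detections; also the confinement radius used to classify
#'   bound molecules.
#' @param min_track_length minimum track length in frames (>= 2); by default
#'   the length counts frames spanned, including gap-closed frames.
#' @param gap_frames number of consecutive frames a molecule may go
#'   undetected without terminating its track (>= 0).
#' @param min_segmentation_length minimum length (frames) of a contiguous
#'   detection run retained within a track.
#' @return data.frame of class `tracking_config`, one row per condition.
#' @seealso [default_tracking_config()] for the published per-condition
#'   values.
#' @export
tracking_config <- function(cycle_times, tracking_radius, min_track_length,
                            gap_frames, min_segmentation_length = 2L) {
  cfg <- data.frame(cycle_time = cycle_times,
                    tracking_radius = tracking_radius,
                    min_track_length = as.integer(min_track_length),
                    gap_frames = as.integer(gap_frames),
                    min_segmentation_length = as.integer(min_segmentation_length))
  if (any(cfg$tracking_radius <= 0)) stop("tracking_radius must be > 0")
  if (any(cfg$min_track_length < 2)) stop("min_track_length must be >= 2")
  if (any(cfg$gap_frames < 0)) stop("gap_frames must be >= 0")
  class(cfg) <- c("tracking_config", "data.frame")
  cfg
}

config_for_condition <- function(config, cycle_time) {
  i <- which(abs(config$cycle_time - cycle_time) < 1e-9)
  if (length(i) != 1L)
    stop(sprintf("no tracking configuration for cycle time %g s", cycle_time))
  config[i, , drop = FALSE]
}

#' Construct a track set
#'
#' Container for linked single-molecule trajectories of one time-lapse
#' condition, the bridge between tracking and survival analysis.
#'
#' @param tracks data.frame with one row per track: `track_id`,
#'   `first_frame`, `last_frame`, `n_detections`, `duration_frames`,
#'   `n_gaps_closed`.
#' @param positions data.frame `track_id, frame, x, y` of the detections.
#' @param cycle_time frame cycle time (s) of the condition.
#' @param total_molecules number of all linked molecules before the minimum
#'   track length filter (the denominator of the "bound/total" report).
#' @param movie_duration movie duration in seconds when known (`NA`
#'   otherwise); lets the spectrum fit model the finite observation window.
#' @return object of class `track_set`.
#' @export
new_track_set <- function(tracks, positions, cycle_time, total_molecules,
                          movie_duration = NA_real_) {
  structure(list(tracks = tracks, positions = positions,
                 cycle_time = cycle_time,
                 total_molecules = as.integer(total_molecules),
                 movie_duration = movie_duration),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("Track set: %d tracks (of %d molecules), cycle time %g s\n",
              nrow(x$tracks), x$total_molecules, x$cycle_time))
  invisible(x)
}

#' Track durations in seconds
#'
#' A track spanning n frames evidences persistence over n - 1 frame cycles,
#' so its duration is `(duration_frames - 1) * cycle_time`.
#' @param ts a [track_set].
#' @return numeric vector of durations in seconds.
#' @export
track_durations <- function(ts) {
  (ts$tracks$duration_frames - 1) * ts$cycle_time
}

#' Link per-frame detections into tracks
#'
#' Greedy globally-nearest-neighbour linking: for each frame, all
#' (active track, new spot) pairs within the tracking radius are linked in
#' order of increasing distance, each track and spot at most once; distance
#' ties break deterministically by earlier track start frame, then lower
#' spot index. A track not extended for more than `gap_frames` consecutive
#' frames is terminated; gap-closed frames contribute to the track duration
#' but add no positions. After linking, contiguous detection runs shorter
#' than `min_segmentation_length` are discarded and tracks are re-split
#' where the remaining runs no longer satisfy the gap rule; finally tracks
#' spanning fewer than `min_track_length` frames are dropped (they still
#' count towards `total_molecules`).
#'
#' @param spots data.frame `frame, x, y` (plus extra columns, ignored),
#'   e.g. from [detect_movie()]; frames 0-based.
#' @param config a [tracking_config()] (or one row of it).
#' @param cycle_time frame cycle time (s) selecting the config row.
#' @param count_gap_frames should `duration_frames` count frames spanned
#'   (including gap-closed frames, default) or detections only?
#' @return a [track_set].
#' @examples
#' spots <- data.frame(frame = c(0, 1, 3, 4), x = 10, y = 10)
#' cfg <- tracking_config(1.6, tracking_radius = 1.75,
#'                        min_track_length = 2, gap_frames = 1)
#' link_tracks(spots, cfg, 1.6)$tracks
#' @export
link_tracks <- function(spots, config, cycle_time,
                        count_gap_frames = TRUE) {
  cfg <- config_for_condition(config, cycle_time)
  radius <- cfg$tracking_radius
  gap <- cfg$gap_frames

  open_last_x <- numeric(); open_last_y <- numeric()
  open_last_f <- integer(); open_start_f <- integer(); open_id <- integer()
  det_track <- integer(nrow(spots))   # track id of each detection
  next_id <- 1L
  frames <- sort(unique(spots$frame))
  spl <- split(seq_len(nrow(spots)), spots$frame)

  for (f in frames) {
    # retire tracks that can no longer be extended at frame f
    alive <- f - open_last_f <= gap + 1L
    open_last_x <- open_last_x[alive]; open_last_y <- open_last_y[alive]
    open_last_f <- open_last_f[alive]; open_start_f <- open_start_f[alive]
    open_id <- open_id[alive]

    rows <- spl[[as.character(f)]]
    sx <- spots$x[rows]; sy <- spots$y[rows]
    ns <- length(rows); nt <- length(open_id)
    linked_spot <- logical(ns)
    if (nt && ns) {
      d2 <- outer(open_last_x, sx, "-")^2 + outer(open_last_y, sy, "-")^2
      pairs <- which(d2 <= radius^2, arr.ind = TRUE)
      if (nrow(pairs)) {
        o <- order(d2[pairs], open_start_f[pairs[, 1]], pairs[, 2])
        pairs <- pairs[o, , drop = FALSE]
        used_t <- logical(nt)
        for (p in seq_len(nrow(pairs))) {
          ti <- pairs[p, 1]; si <- pairs[p, 2]
          if (used_t[ti] || linked_spot[si]) next
          used_t[ti] <- TRUE; linked_spot[si] <- TRUE
          det_track[rows[si]] <- open_id[ti]
          open_last_x[ti] <- sx[si]; open_last_y[ti] <- sy[si]
          open_last_f[ti] <- f
        }
      }
    }
    if (any(!linked_spot)) {
      new_idx <- which(!linked_spot)
      ids <- seq.int(next_id, length.out = length(new_idx))
      next_id <- next_id + length(new_idx)
      det_track[rows[new_idx]] <- ids
      open_last_x <- c(open_last_x, sx[new_idx])
      open_last_y <- c(open_last_y, sy[new_idx])
      open_last_f <- c(open_last_f, rep(f, length(new_idx)))
      open_start_f <- c(open_start_f, rep(f, length(new_idx)))
      open_id <- c(open_id, ids)
    }
  }

  pos <- data.frame(track_id = det_track, frame = spots$frame,
                    x = spots$x, y = spots$y)
  pos <- pos[order(pos$track_id, pos$frame), , drop = FALSE]
  pos <- .filter_segments(pos, cfg$min_segmentation_length, gap)
  rownames(pos) <- NULL

  if (nrow(pos)) {
    first <- tapply(pos$frame, pos$track_id, min)
    last <- tapply(pos$frame, pos$track_id, max)
    ndet <- tapply(pos$frame, pos$track_id, length)
    span <- as.integer(last - first + 1)
    tracks <- data.frame(track_id = as.integer(names(first)),
                         first_frame = as.integer(first),
                         last_frame = as.integer(last),
                         n_detections = as.integer(ndet),
                         duration_frames = if (count_gap_frames) span else
                           as.integer(ndet),
                         n_gaps_closed = span - as.integer(ndet))
  } else {
    tracks <- data.frame(track_id = integer(), first_frame = integer(),
                         last_frame = integer(), n_detections = integer(),
                         duration_frames = integer(), n_gaps_closed = integer())
  }
  total <- nrow(tracks)
  keep <- tracks$duration_frames >= cfg$min_track_length
  tracks <- tracks[keep, , drop = FALSE]
  pos <- pos[pos$track_id %in% tracks$track_id, , drop = FALSE]
  rownames(tracks) <- rownames(pos) <- NULL
  new_track_set(tracks, pos, cycle_time, total)
}

# Drop contiguous detection runs shorter than min_seg from each track and
# re-split tracks where the surviving runs violate the gap rule. Track ids
# of split pieces get a fractional suffix re-coded to new integer ids.
.filter_segments <- function(pos, min_seg, gap) {
  if (min_seg <= 1L || !nrow(pos)) return(pos)
  pieces <- split(pos, pos$track_id)
  out <- vector("list", length(pieces))
  next_extra <- max(pos$track_id) + 1L
  for (pi in seq_along(pieces)) {
    p <- pieces[[pi]]
    seg <- cumsum(c(1L, diff(p$frame) != 1L))
    seg_len <- tabulate(seg)
    keep <- seg_len[seg] >= min_seg
    p <- p[keep, , drop = FALSE]
    if (!nrow(p)) { out[[pi]] <- p; next }
    # re-split where surviving runs are farther apart than the gap rule
    brk <- cumsum(c(0L, diff(p$frame) > gap + 1L))
    if (max(brk) > 0L) {
      ids <- p$track_id[1] * (brk == 0L)
      extra <- seq.int(next_extra, length.out = max(brk))
      next_extra <- next_extra + max(brk)
      p$track_id <- ifelse(brk == 0L, p$track_id, extra[pmax(brk, 1L)])
    }
    out[[pi]] <- p
  }
  res <- do.call(rbind, out)
  res[order(res$track_id, res$frame), , drop = FALSE]
}

#' Classify bound molecules by confinement
#'
#' A track is classified as bound when every detection stays within the
#' tracking radius of the track's first detection and the track spans at
#' least `min_track_length` frames; freely diffusing molecules violate the
#' confinement within a frame or two. Counts are reported in the
#' "bound/total" convention where the total is the number of all linked
#' molecules of the condition.
#'
#' @param ts a [track_set] from [link_tracks()] or [as_track_set()].
#' @param config a [tracking_config()].
#' @return list with elements `bound` (a [track_set] of the bound tracks),
#'   `bound_count`, `total_molecule_count` and `label`
#'   (e.g. `"1459/19835"`).
#' @export
classify_bound <- function(ts, config) {
  cfg <- config_for_condition(config, ts$cycle_time)
  ids <- ts$tracks$track_id
  confined <- vapply(split(ts$positions, ts$positions$track_id), function(p) {
    all((p$x - p$x[1])^2 + (p$y - p$y[1])^2 <= cfg$tracking_radius^2)
  }, logical(1))
  confined <- confined[match(as.character(ids), names(confined))]
  bound_keep <- confined & ts$tracks$duration_frames >= cfg$min_track_length
  bound_tracks <- ts$tracks[bound_keep, , drop = FALSE]
  bound_pos <- ts$positions[ts$positions$track_id %in% bound_tracks$track_id, ,
                            drop = FALSE]
  rownames(bound_tracks) <- rownames(bound_pos) <- NULL
  bound <- new_track_set(bound_tracks, bound_pos, ts$cycle_time,
                         ts$total_molecules)
  list(bound = bound,
       bound_count = nrow(bound_tracks),
       total_molecule_count = ts$total_molecules,
       label = sprintf("%d/%d", nrow(bound_tracks), ts$total_molecules))
}
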