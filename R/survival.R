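#' Fluorescence survival-time distribution of one condition
#'
#' Assembles bound-track durations into the empirical survival function:
#' for each observed duration t, the number of tracks lasting at least t.
#' Durations follow the `(frames - 1) * cycle_time` convention (time spanned
#' between first and last detection), so the function is an exact step
#' function starting at `n_tracks` with no binning.
#'
#' @param x a [track_set], or a numeric vector of durations in seconds
#'   (then `cycle_time` must be given).
#' @param cycle_time frame cycle time in seconds (taken from the track set
#'   when `x` is one).
#' @param movie_duration movie duration in seconds when known (taken from
#'   the track set when `x` is one); carried along so the spectrum fit can
#'   model the finite observation window.
#' @return object of class `survival_dist`: list with `cycle_time`,
#'   `durations` (sorted unique observed durations, s), `counts` (number of
#'   tracks with duration >= each), `n_tracks` and `movie_duration`. A
#'   zero-track input yields an empty distribution with a warning.
#' @examples
#' sd <- build_survival(c(0.4, 0.4, 1.2), cycle_time = 0.4)
#' sd$counts
#' @export
build_survival <- function(x, cycle_time = NULL, movie_duration = NA_real_) {
  if (inherits(x, "track_set")) {
    durations <- track_durations(x)
    cycle_time <- x$cycle_time
    movie_duration <- x$movie_duration %||% NA_real_
  } else {
    durations <- as.numeric(x)
    if (is.null(cycle_time)) stop("cycle_time is required for raw durations")
  }
  if (!length(durations)) {
    warning(sprintf("no tracks at cycle time %g s: empty survival distribution",
                    cycle_time))
    return(structure(list(cycle_time = cycle_time, durations = numeric(),
                          counts = integer(), n_tracks = 0L,
                          movie_duration = movie_duration),
                     class = "survival_dist"))
  }
  d <- sort(unique(durations))
  # counts surviving >= d: total minus those strictly shorter
  shorter <- findInterval(d - 1e-12, sort(durations))
  structure(list(cycle_time = cycle_time, durations = d,
                 counts = length(durations) - shorter,
                 n_tracks = length(durations),
                 movie_duration = movie_duration),
            class = "survival_dist")
}

#' @export
print.survival_dist <- function(x, ...) {
  cat(sprintf("Survival distribution: %d tracks, cycle time %g s, durations %g..%g s\n",
              x$n_tracks, x$cycle_time,
              if (length(x$durations)) min(x$durations) else NA,
              if (length(x$durations)) max(x$durations) else NA))
  invisible(x)
}

#' Merge survival distributions of the same condition
#'
#' The survival function of pooled track sets equals the sum of the
#' individual survival functions.
#' @param ... `survival_dist` objects with identical cycle times.
#' @return a `survival_dist`.
#' @export
merge_survival <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "survival_dist")))
  ct <- unique(vapply(parts, `[[`, numeric(1), "cycle_time"))
  if (length(ct) != 1L) stop("cannot merge different conditions")
  durations <- unlist(lapply(parts, function(p)
    rep(p$durations, -diff(c(p$counts, 0L)))))
  md <- unique(vapply(parts, function(p) p$movie_duration %||% NA_real_,
                      numeric(1)))
  build_survival(durations, cycle_time = ct,
                 movie_duration = if (length(md) == 1L) md else NA_real_)
}

#' Evaluate an empirical survival function
#' @param sd a `survival_dist`.
#' @param t times (s) at which to evaluate.
#' @return number of tracks with duration >= t (right-continuous step
#'   function; equals `n_tracks` for t below the smallest duration).
#' @export
survival_at <- function(sd, t) {
  if (!length(sd$durations)) return(rep(0L, length(t)))
  j <- findInterval(t - 1e-12, sd$durations)  # durations strictly below t
  ifelse(j >= length(sd$counts), 0L, sd$counts[pmin(j + 1L, length(sd$counts))])
}

#' Build survival distributions for a list of track sets
#'
#' Convenience wrapper applying [build_survival()] per condition; empty
#' conditions are flagged with a warning and excluded.
#' @param track_sets list of [track_set] objects (distinct conditions).
#' @return list of `survival_dist`, ordered by cycle time.
#' @export
build_survivals <- function(track_sets) {
  out <- lapply(track_sets, build_survival)
  out <- out[vapply(out, function(s) s$n_tracks > 0L, logical(1))]
  out[order(vapply(out, `[[`, numeric(1), "cycle_time"))]
}
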