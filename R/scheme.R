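#' Imaging scheme for time-lapse single-molecule acquisition
#'
#' A time-lapse illumination schedule consists of a fixed camera integration
#' time and a set of acquisition conditions, each defined by a frame cycle
#' time (integration plus dark period) and a total movie duration. Varying
#' the dark period while keeping the integration time fixed lets dissociation
#' be separated from photobleaching, because bleaching accrues only while the
#' laser is on.
#'
#' @param cycle_times numeric vector of frame cycle times tau_tl in seconds,
#'   strictly increasing; each must be at least `integration_time`.
#' @param movie_durations numeric vector (same length) of movie durations in
#'   seconds; each condition must cover at least 2 frames.
#' @param integration_time camera integration time in seconds (default 0.05,
#'   i.e. 50 ms).
#' @param pixel_size physical length per pixel, recorded for provenance;
#'   all positions and radii in this package are in pixel units.
#'
#' @return An object of class `imaging_scheme`: a list with elements
#'   `integration_time`, `cycle_times`, `movie_durations`, `n_frames`
#'   (frames per condition, floor of duration/cycle time) and `pixel_size`.
#' @examples
#' sch <- imaging_scheme(c(0.1, 0.4, 1.6), c(30, 120, 480))
#' sch$n_frames
#' @export
imaging_scheme <- function(cycle_times, movie_durations,
                           integration_time = 0.05, pixel_size = 1) {
  stopifnot(is.numeric(cycle_times), is.numeric(movie_durations),
            length(cycle_times) == length(movie_durations),
            length(cycle_times) >= 1)
  if (!is.numeric(integration_time) || length(integration_time) != 1L ||
      integration_time <= 0)
    stop("integration_time must be a single positive number (seconds)")
  if (any(cycle_times < integration_time))
    stop("every cycle time must be >= the integration time")
  if (is.unsorted(cycle_times, strictly = TRUE))
    stop("cycle times must be strictly increasing")
  n_frames <- floor(movie_durations / cycle_times)
  if (any(n_frames < 2))
    stop("each condition must cover at least 2 frames (movie_duration / cycle_time >= 2)")
  structure(list(integration_time = integration_time,
                 cycle_times = as.numeric(cycle_times),
                 movie_durations = as.numeric(movie_durations),
                 n_frames = as.integer(n_frames),
                 pixel_size = pixel_size),
            class = "imaging_scheme")
}

#' @export
print.imaging_scheme <- function(x, ...) {
  cat("Time-lapse imaging scheme\n")
  cat(sprintf("  integration time: %g s\n", x$integration_time))
  for (i in seq_along(x$cycle_times))
    cat(sprintf("  condition %d: cycle %g s, movie %g s (%d frames)\n",
                i, x$cycle_times[i], x$movie_durations[i], x$n_frames[i]))
  invisible(x)
}

#' Number of conditions in an imaging scheme
#' @param scheme an [imaging_scheme()].
#' @return integer count of time-lapse conditions.
#' @export
n_conditions <- function(scheme) length(scheme$cycle_times)

# movie duration lookup used by several stages
check_condition <- function(scheme, condition) {
  if (!inherits(scheme, "imaging_scheme")) stop("not an imaging_scheme")
  if (!(is.numeric(condition) && length(condition) == 1L &&
        condition >= 1 && condition <= n_conditions(scheme)))
    stop("invalid condition index")
  as.integer(condition)
}
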