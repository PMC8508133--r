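# Plain-text readers/writers for the pipeline's intermediate artifacts.
# Tracks and spots travel as CSV, schemes/spectra/reports as JSON, movies as
# multi-page TIFF (see render.R).

#' Write a track set to CSV
#'
#' Columns `track_id,frame,x,y,condition` (condition = cycle time in s).
#' @param ts a [track_set].
#' @param path output CSV path.
#' @export
write_tracks_csv <- function(ts, path) {
  df <- ts$positions
  df$condition <- ts$cycle_time
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a track table CSV into track sets
#'
#' Expects columns `track_id` (or `molecule_id`), `frame`, `x`, `y`,
#' `condition`; returns one [track_set] per condition. Durations count
#' frames spanned between first and last detection.
#' @param path CSV path.
#' @return named list of [track_set], names = cycle times.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"track_id" %in% names(df) && "molecule_id" %in% names(df))
    names(df)[names(df) == "molecule_id"] <- "track_id"
  need <- c("track_id", "frame", "x", "y", "condition")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns ", paste(need, collapse = ","))
  out <- lapply(split(df, df$condition), function(d) {
    first <- tapply(d$frame, d$track_id, min)
    last <- tapply(d$frame, d$track_id, max)
    ndet <- tapply(d$frame, d$track_id, length)
    tracks <- data.frame(track_id = as.integer(names(first)),
                         first_frame = as.integer(first),
                         last_frame = as.integer(last),
                         n_detections = as.integer(ndet),
                         duration_frames = as.integer(last - first + 1),
                         n_gaps_closed = as.integer(last - first + 1 - ndet))
    new_track_set(tracks, d[, c("track_id", "frame", "x", "y")],
                  cycle_time = d$condition[1],
                  total_molecules = nrow(tracks))
  })
  out[order(as.numeric(names(out)))]
}

#' Write a survival distribution to CSV (`duration_s,survival_count`)
#' @param sd a `survival_dist`.
#' @param path output CSV path.
#' @export
write_survival_csv <- function(sd, path) {
  utils::write.csv(data.frame(duration_s = sd$durations,
                              survival_count = sd$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a rate spectrum to JSON
#' @param spectrum a `rate_spectrum`.
#' @param path output JSON path.
#' @export
write_spectrum_json <- function(spectrum, path) {
  jsonlite::write_json(
    list(rates = spectrum$rates,
         event_weights = spectrum$event_weights,
         state_weights = spectrum$state_weights,
         bleach_number = spectrum$bleach_number,
         residual = spectrum$residual,
         cycle_times = spectrum$cycle_times),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an imaging scheme to JSON
#' @param scheme an [imaging_scheme()].
#' @param path output JSON path.
#' @export
write_scheme_json <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an imaging scheme from JSON
#' @param path JSON path written by [write_scheme_json()].
#' @return an [imaging_scheme()].
#' @export
read_scheme_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  imaging_scheme(x$cycle_times, x$movie_durations, x$integration_time,
                 if (is.null(x$pixel_size)) 1 else x$pixel_size)
}
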