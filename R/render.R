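#' Render a simulated movie from tracks
#'
#' Renders each visible molecule as a 2-D Gaussian point-spread function of
#' width `psf_sigma` on a constant background, with optional per-pixel
#' Poisson shot noise. Frame count equals the condition's
#' `floor(movie_duration / cycle_time)`. An empty track list yields a valid
#' all-background movie.
#'
#' @param positions data.frame with columns `frame`, `x`, `y` (pixels,
#'   frames 0-based), e.g. the `positions` element of [simulate_tracks()].
#' @param scheme an [imaging_scheme()].
#' @param condition condition index within `scheme`.
#' @param field_size `c(width, height)` in pixels.
#' @param psf_sigma Gaussian PSF standard deviation in pixels (> 0).
#' @param amplitude peak intensity of a single molecule (photons).
#' @param background constant background level per pixel (> 0).
#' @param noise apply Poisson shot noise per pixel?
#' @param seed optional integer seed; rendering is deterministic given it.
#'
#' @return An object of class `sm_movie`: a 3-D array
#'   `[y, x, frame]` with attributes `cycle_time` and `integration_time`.
#' @examples
#' pos <- data.frame(frame = 0:4, x = 20.3, y = 11.7)
#' sch <- imaging_scheme(0.1, 1)
#' mov <- render_movie(pos, sch, 1, field_size = c(40, 30), noise = FALSE)
#' dim(mov)
#' @export
render_movie <- function(positions, scheme, condition,
                         field_size = c(128, 128), psf_sigma = 1.1,
                         amplitude = 200, background = 10,
                         noise = TRUE, seed = NULL) {
  condition <- check_condition(scheme, condition)
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (background <= 0) stop("background_level must be > 0")
  if (!is.null(seed)) set.seed(seed)
  nx <- as.integer(field_size[1]); ny <- as.integer(field_size[2])
  n_frames <- scheme$n_frames[condition]
  movie <- array(background, dim = c(ny, nx, n_frames))
  if (!is.null(positions) && nrow(positions)) {
    w <- ceiling(4 * psf_sigma)
    keep <- positions$frame >= 0 & positions$frame < n_frames
    positions <- positions[keep, , drop = FALSE]
    for (r in seq_len(nrow(positions))) {
      x <- positions$x[r]; y <- positions$y[r]
      f <- positions$frame[r] + 1L
      cx <- round(x); cy <- round(y)
      xs <- max(0, cx - w):min(nx - 1, cx + w)
      ys <- max(0, cy - w):min(ny - 1, cy + w)
      if (!length(xs) || !length(ys)) next
      gx <- exp(-(xs - x)^2 / (2 * psf_sigma^2))
      gy <- exp(-(ys - y)^2 / (2 * psf_sigma^2))
      movie[ys + 1L, xs + 1L, f] <- movie[ys + 1L, xs + 1L, f] +
        amplitude * outer(gy, gx)
    }
  }
  if (noise) movie[] <- stats::rpois(length(movie), movie)
  structure(movie, class = "sm_movie",
            cycle_time = scheme$cycle_times[condition],
            integration_time = scheme$integration_time)
}

#' Write a movie as a multi-page grayscale TIFF
#'
#' Frames are stored in time order, intensities scaled by `1/scale` into the
#' [0, 1] range of 16-bit TIFF samples. `scale` defaults to the smallest
#' power of two not less than the movie maximum so the round trip through
#' [read_movie_tiff()] is exact to 16-bit quantization.
#'
#' @param movie an `sm_movie` (or 3-D array `[y, x, frame]`).
#' @param path output file path.
#' @param scale intensity corresponding to full scale; stored nowhere, so
#'   pass the same value to [read_movie_tiff()].
#' @return `scale`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, scale = NULL) {
  if (is.null(scale)) scale <- 2^ceiling(log2(max(movie, 1)))
  frames <- lapply(seq_len(dim(movie)[3]),
                   function(f) pmin(pmax(movie[, , f] / scale, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(scale)
}

#' Read a multi-page grayscale TIFF movie
#' @param path TIFF file path.
#' @param scale intensity corresponding to full scale (see
#'   [write_movie_tiff()]).
#' @return 3-D array `[y, x, frame]`.
#' @export
read_movie_tiff <- function(path, scale = 1) {
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (length(dim(fr)) == 3L) fr <- fr[, , 1]
    arr[, , f] <- fr * scale
  }
  arr
}
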