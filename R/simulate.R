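#' Simulate single-molecule tracks under a time-lapse condition
#'
#' Kinetic Monte Carlo simulation of the observation process that time-lapse
#' illumination is designed to disentangle. Each bound molecule draws a
#' binding state i with probability `state_probs[i]`, a dwell time from
#' Exponential(`rates[i]`) and a uniform appearance time within the movie;
#' it is observed at every acquired frame while bound, and independently
#' survives each illuminated frame with probability
#' `exp(-bleach_rate * integration_time)`. Observation ends at dissociation,
#' bleaching or the end of the movie, whichever comes first. Bound positions
#' jitter around a fixed binding site by `localization_sd` per frame.
#' Unbound molecules (simulated when `bound_fraction < 1` and
#' `include_diffusers = TRUE`) perform 2-D Brownian motion with coefficient
#' `diffusion`, reflected at the field boundary, and bleach at the same
#' per-frame rate. Bleaching is applied only during illuminated intervals,
#' never during dark periods.
#'
#' @param truth a [ground_truth()].
#' @param scheme an [imaging_scheme()].
#' @param condition index of the time-lapse condition within `scheme`.
#' @param n_molecules number of bound binding events to simulate (>= 1).
#' @param field_size integer vector `c(width, height)` in pixels; the full
#'   field plays the role of one nucleus.
#' @param include_diffusers simulate unbound molecules as well? Their count
#'   is `n_molecules * (1 - bound_fraction) / bound_fraction`, rounded.
#' @param seed optional integer; the simulation is deterministic given it.
#'
#' @return An object of class `sim_tracks`: a list with
#'   \describe{
#'     \item{molecules}{data.frame, one row per molecule: `molecule_id`,
#'       `state_index` (0 = unbound diffuser), `appearance_time` (s),
#'       `true_dwell` (s), `first_frame`, `n_frames_observed`, `end_cause`
#'       (`"dissociated"`, `"bleached"`, `"movie_end"` or `"unobserved"`),
#'       `site_x`, `site_y`.}
#'     \item{positions}{data.frame `molecule_id, frame, x, y` (pixels,
#'       frames 0-based), only molecules observed for >= 1 frame.}
#'     \item{condition, cycle_time, n_frames, scheme, truth, field_size}{metadata.}
#'   }
#' @examples
#' truth <- ground_truth(rates = c(0.01, 0.5), state_probs = c(0.4, 0.6),
#'                       bleach_rate = 0.5)
#' sch <- construct_scheme("RBPJ")
#' sim <- simulate_tracks(truth, sch, condition = 3, n_molecules = 100, seed = 1)
#' table(sim$molecules$end_cause)
#' @export
simulate_tracks <- function(truth, scheme, condition, n_molecules,
                            field_size = c(128, 128),
                            include_diffusers = truth$bound_fraction < 1,
                            seed = NULL) {
  if (!inherits(truth, "ground_truth")) stop("truth must be a ground_truth object")
  condition <- check_condition(scheme, condition)
  if (!is.numeric(n_molecules) || length(n_molecules) != 1L || n_molecules < 1)
    stop("n_molecules must be >= 1")
  n_molecules <- as.integer(n_molecules)
  field_size <- as.numeric(field_size)
  if (length(field_size) != 2L || any(field_size <= 0))
    stop("field_size must be two positive numbers (zero-area field rejected)")
  if (!is.null(seed)) set.seed(seed)

  tau <- scheme$cycle_times[condition]
  t_int <- scheme$integration_time
  n_frames <- scheme$n_frames[condition]
  t_movie <- scheme$movie_durations[condition]
  a <- truth$bleach_rate * t_int          # bleach number per illuminated frame
  p_keep <- exp(-a)

  m <- n_molecules
  state <- sample.int(length(truth$rates), m, replace = TRUE,
                      prob = truth$state_probs)
  k <- truth$rates[state]
  dwell <- rep(Inf, m)
  pos_k <- k > 0
  if (any(pos_k)) dwell[pos_k] <- stats::rexp(sum(pos_k), rate = k[pos_k])
  u <- stats::runif(m, 0, t_movie)

  # frames are acquired at times f * tau, f = 0 .. n_frames - 1
  f0 <- ceiling(u / tau)
  n_dwell <- floor((u + dwell - f0 * tau) / tau) + 1  # frames while bound
  n_dwell[f0 * tau > u + dwell] <- 0
  # per-frame single-step bleaching: bleach after frame j with prob 1 - p_keep
  n_bleach <- if (a > 0) stats::rgeom(m, 1 - p_keep) + 1 else rep(Inf, m)
  n_movie <- pmax(n_frames - f0, 0)       # frames remaining in the movie
  n_obs <- pmin(n_dwell, n_bleach, n_movie)

  end_cause <- rep("unobserved", m)
  obs <- n_obs >= 1
  end_cause[obs & n_obs == n_dwell] <- "dissociated"
  end_cause[obs & end_cause == "unobserved" & n_obs == n_bleach] <- "bleached"
  end_cause[obs & end_cause == "unobserved"] <- "movie_end"

  margin <- min(3, field_size / 4)
  site_x <- stats::runif(m, margin, field_size[1] - margin)
  site_y <- stats::runif(m, margin, field_size[2] - margin)

  molecules <- data.frame(
    molecule_id = seq_len(m), state_index = state,
    appearance_time = u, true_dwell = dwell,
    first_frame = ifelse(obs, f0, NA_integer_),
    n_frames_observed = as.integer(ifelse(obs, n_obs, 0L)),
    end_cause = end_cause, site_x = site_x, site_y = site_y)

  # expand bound observations to per-frame positions
  n_obs_i <- molecules$n_frames_observed[obs]
  if (length(n_obs_i)) {
    id <- rep(molecules$molecule_id[obs], n_obs_i)
    frame <- unlist(lapply(which(obs), function(i)
      seq.int(f0[i], length.out = n_obs[i])), use.names = FALSE)
    n_pos <- length(id)
    positions <- data.frame(
      molecule_id = id, frame = as.integer(frame),
      x = rep(site_x[obs], n_obs_i) + stats::rnorm(n_pos, 0, truth$localization_sd),
      y = rep(site_y[obs], n_obs_i) + stats::rnorm(n_pos, 0, truth$localization_sd))
  } else {
    positions <- data.frame(molecule_id = integer(), frame = integer(),
                            x = numeric(), y = numeric())
  }

  if (include_diffusers && truth$bound_fraction < 1) {
    n_diff <- round(m * (1 - truth$bound_fraction) / truth$bound_fraction)
    if (n_diff >= 1) {
      dd <- .simulate_diffusers(truth, n_diff, n_frames, tau, p_keep,
                                field_size, id_offset = m)
      molecules <- rbind(molecules, dd$molecules)
      positions <- rbind(positions, dd$positions)
    }
  }

  positions <- positions[order(positions$molecule_id, positions$frame), ,
                         drop = FALSE]
  rownames(positions) <- NULL
  structure(list(molecules = molecules, positions = positions,
                 condition = condition, cycle_time = tau,
                 n_frames = n_frames, scheme = scheme, truth = truth,
                 field_size = field_size),
            class = "sim_tracks")
}

# Unbound molecules: Brownian motion, present from frame 0, reflected at the
# field boundary, bleaching as for bound molecules.
.simulate_diffusers <- function(truth, n_diff, n_frames, tau, p_keep,
                                field_size, id_offset) {
  step_sd <- sqrt(2 * truth$diffusion * tau)
  n_bleach <- if (p_keep < 1) stats::rgeom(n_diff, 1 - p_keep) + 1 else
    rep(Inf, n_diff)
  n_obs <- pmin(n_bleach, n_frames)
  mol <- data.frame(
    molecule_id = id_offset + seq_len(n_diff), state_index = 0L,
    appearance_time = 0, true_dwell = Inf, first_frame = 0L,
    n_frames_observed = as.integer(n_obs),
    end_cause = ifelse(n_obs < n_frames, "bleached", "movie_end"),
    site_x = NA_real_, site_y = NA_real_)
  reflect <- function(z, lo, hi) {
    span <- hi - lo
    z <- (z - lo) %% (2 * span)
    lo + ifelse(z > span, 2 * span - z, z)
  }
  pos <- lapply(seq_len(n_diff), function(i) {
    n <- n_obs[i]
    x <- cumsum(c(stats::runif(1, 0, field_size[1]), stats::rnorm(n - 1, 0, step_sd)))
    y <- cumsum(c(stats::runif(1, 0, field_size[2]), stats::rnorm(n - 1, 0, step_sd)))
    data.frame(molecule_id = id_offset + i, frame = seq.int(0L, length.out = n),
               x = reflect(x, 0, field_size[1]), y = reflect(y, 0, field_size[2]))
  })
  list(molecules = mol, positions = do.call(rbind, pos))
}

#' @export
print.sim_tracks <- function(x, ...) {
  cat(sprintf("Simulated tracks: %d molecules, cycle time %g s, %d frames\n",
              nrow(x$molecules), x$cycle_time, x$n_frames))
  print(table(x$molecules$end_cause))
  invisible(x)
}

#' Ground-truth track set from a simulation
#'
#' Converts simulated molecule observations into a [track_set] (one track per
#' molecule observed for at least one frame), bypassing detection and
#' linking. This is the direct track-table route used for survival analysis
#' at scale; the movie route (render, detect, link) serves to validate the
#' image-processing stages on small fields.
#'
#' @param sim a [simulate_tracks()] result.
#' @param bound_only keep only molecules bound to a site (drop diffusers).
#' @return a [track_set].
#' @export
as_track_set <- function(sim, bound_only = TRUE) {
  stopifnot(inherits(sim, "sim_tracks"))
  mol <- sim$molecules[sim$molecules$n_frames_observed >= 1L, , drop = FALSE]
  if (bound_only) mol <- mol[mol$state_index > 0L, , drop = FALSE]
  tracks <- data.frame(
    track_id = mol$molecule_id,
    first_frame = mol$first_frame,
    last_frame = mol$first_frame + mol$n_frames_observed - 1L,
    n_detections = mol$n_frames_observed,
    duration_frames = mol$n_frames_observed,
    n_gaps_closed = 0L)
  pos <- sim$positions[sim$positions$molecule_id %in% mol$molecule_id, ,
                       drop = FALSE]
  names(pos)[names(pos) == "molecule_id"] <- "track_id"
  new_track_set(tracks, pos, cycle_time = sim$cycle_time,
                total_molecules = nrow(mol),
                movie_duration = sim$scheme$movie_durations[sim$condition])
}

#' Expected fraction of binding events yielding a bound track
#'
#' Closed-form approximation to the probability that a simulated binding
#' event is observed for at least `min_track_length` frames under a given
#' condition: for state i with rate k, the event must fall on the frame grid
#' (capture factor `(1 - exp(-k tau)) / (k tau)` for the random phase between
#' appearance and the first acquired frame), survive `(m - 1)` further cycles
#' of dissociation and of bleaching, and appear early enough in the movie.
#' Used to scale simulations to a target bound-track count.
#'
#' @inheritParams simulate_tracks
#' @param min_track_length minimum track length in frames.
#' @return probability in (0, 1].
#' @export
expected_bound_fraction <- function(truth, scheme, condition, min_track_length) {
  condition <- check_condition(scheme, condition)
  tau <- scheme$cycle_times[condition]
  t_movie <- scheme$movie_durations[condition]
  a <- bleach_number(truth, scheme)
  m <- min_track_length
  k <- truth$rates
  capture <- ifelse(k > 0, -expm1(-k * tau) / (k * tau), 1)
  p <- capture * exp(-k * (m - 1) * tau) * exp(-a * (m - 1)) *
    max(0, 1 - (m - 1) * tau / t_movie)
  sum(truth$state_probs * p)
}
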