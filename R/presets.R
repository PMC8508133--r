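# Published acquisition schedules and tracking settings for the three
# constructs studied by single-molecule time-lapse imaging (RBPJ, the
# DNA-binding-defective mutant RBPJ(R218H), and the pancreatic paralog
# RBPJL), plus the reported per-condition molecule counts used to scale
# recovery simulations.

# movie duration by cycle time: 30 s (0.1), 120 s (0.4), 480 s (1.6),
# 960 s (3.2 and 6.4), 1400 s (14)
.movie_duration_table <- c("0.1" = 30, "0.4" = 120, "1.6" = 480,
                           "3.2" = 960, "6.4" = 960, "14" = 1400)

.construct_cycles <- list(
  "RBPJ"       = c(0.1, 0.4, 1.6, 6.4, 14),
  "RBPJ-R218H" = c(0.1, 0.4, 1.6, 6.4),   # 14 s excluded: bound events too rare
  "RBPJL"      = c(0.1, 0.4, 3.2, 14)
)

# Figure-4-legend counts (bound molecules / total molecules) per condition
.construct_counts <- list(
  "RBPJ"       = list(bound = c(1459, 1149, 2648, 1584, 434),
                      total = c(19835, 19921, 26782, 19203, 5593)),
  "RBPJ-R218H" = list(bound = c(1329, 1064, 1978, 882),
                      total = c(16990, 20562, 22143, 11619)),
  "RBPJL"      = list(bound = c(975, 940, 878, 525),
                      total = c(19647, 19921, 12865, 7662))
)

# reported slowest-cluster binding times (s), the recovery anchors
.construct_slow_time <- c("RBPJ" = 910, "RBPJ-R218H" = 194, "RBPJL" = 465)

.match_construct <- function(construct) {
  match.arg(construct, names(.construct_cycles))
}

#' Published imaging scheme for a construct
#'
#' Returns the time-lapse acquisition schedule used for one of the three
#' imaged constructs: 50 ms integration; cycle times 0.1/0.4/1.6/6.4/14 s
#' for RBPJ, 0.1/0.4/1.6/6.4 s for RBPJ(R218H) (the 14 s condition was
#' dropped because long-lived binding events were extremely rare for this
#' DNA-binding mutant) and 0.1/0.4/3.2/14 s for RBPJL; movie durations
#' 30/120/480/960/960/1400 s for cycle times 0.1/0.4/1.6/3.2/6.4/14 s.
#'
#' @param construct one of `"RBPJ"`, `"RBPJ-R218H"`, `"RBPJL"`.
#' @return an [imaging_scheme()].
#' @examples
#' construct_scheme("RBPJL")$cycle_times
#' @export
construct_scheme <- function(construct = c("RBPJ", "RBPJ-R218H", "RBPJL")) {
  construct <- .match_construct(construct)
  cyc <- .construct_cycles[[construct]]
  imaging_scheme(cyc, unname(.movie_duration_table[as.character(cyc)]))
}

#' Default per-condition tracking settings
#'
#' Tracking parameters as a function of the frame cycle time, following the
#' published per-condition table: tracking radius 0.9 px (0.1 s tl),
#' 1.19 px (0.4 s), 1.75 px (1.6 s), 2.4 px (3.2 s), 2.8 px (6.4 s),
#' 3.1 px (14 s); minimum track length 3 frames for the 0.1 s and 0.4 s
#' conditions, 2 frames otherwise; 2 gap frames for 0.1 s, 1 otherwise;
#' minimum segmentation length 2 throughout. Cycle times outside the
#' published set get a radius interpolated linearly in log(cycle time).
#'
#' @param cycle_times numeric vector of frame cycle times in seconds.
#' @return a `data.frame` with one row per condition and columns
#'   `cycle_time`, `tracking_radius`, `min_track_length`, `gap_frames`,
#'   `min_segmentation_length`.
#' @examples
#' default_tracking_config(c(0.1, 1.6, 14))
#' @export
default_tracking_config <- function(cycle_times) {
  known_tau <- c(0.1, 0.4, 1.6, 3.2, 6.4, 14)
  known_rad <- c(0.9, 1.19, 1.75, 2.4, 2.8, 3.1)
  radius <- stats::approx(log(known_tau), known_rad, xout = log(cycle_times),
                          rule = 2)$y
  idx <- match(cycle_times, known_tau)
  radius[!is.na(idx)] <- known_rad[idx[!is.na(idx)]]
  tracking_config(cycle_times = cycle_times,
                  tracking_radius = radius,
                  min_track_length = ifelse(cycle_times <= 0.4, 3L, 2L),
                  gap_frames = ifelse(cycle_times <= 0.1, 2L, 1L),
                  min_segmentation_length = 2L)
}

#' Ground truth anchored at a construct's reported binding time
#'
#' Builds a two-state simulation truth whose slowest state has the binding
#' time reported for the construct (910 s for RBPJ, 194 s for RBPJ(R218H),
#' 465 s for RBPJL), plus one faster state at 0.1 /s carrying 70% of the
#' binding events, with bleach rate 1 /s of illuminated time (bleach number
#' 0.05 per 50 ms frame). These are the conditions the recovery studies
#' simulate; see the methods vignette for the rationale behind the faster
#' state and the bleach number.
#'
#' @inheritParams construct_scheme
#' @param slow_event_prob event probability of the slowest state.
#' @param fast_rate dissociation rate of the faster state, 1/s.
#' @param bleach_rate photobleaching rate, 1/s of illuminated time.
#' @return a [ground_truth()].
#' @examples
#' construct_truth("RBPJ")
#' @export
construct_truth <- function(construct = c("RBPJ", "RBPJ-R218H", "RBPJL"),
                            slow_event_prob = 0.3, fast_rate = 0.1,
                            bleach_rate = 1.0) {
  construct <- .match_construct(construct)
  ground_truth(rates = c(1 / .construct_slow_time[[construct]], fast_rate),
               state_probs = c(slow_event_prob, 1 - slow_event_prob),
               bleach_rate = bleach_rate,
               bound_fraction = 1)
}

#' Reported per-condition molecule counts for a construct
#'
#' The published per-condition counts of bound molecules and of all detected
#' molecules ("bound/total"), used to scale recovery simulations to the same
#' data volume as the imaging experiment.
#'
#' @inheritParams construct_scheme
#' @return data.frame with columns `cycle_time`, `bound`, `total`.
#' @export
construct_counts <- function(construct = c("RBPJ", "RBPJ-R218H", "RBPJL")) {
  construct <- .match_construct(construct)
  data.frame(cycle_time = .construct_cycles[[construct]],
             bound = .construct_counts[[construct]]$bound,
             total = .construct_counts[[construct]]$total)
}

#' Reported slowest-cluster binding time for a construct
#' @inheritParams construct_scheme
#' @return numeric, seconds.
#' @export
construct_binding_time <- function(construct = c("RBPJ", "RBPJ-R218H", "RBPJL")) {
  .construct_slow_time[[.match_construct(construct)]]
}
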