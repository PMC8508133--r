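#' Ground-truth binding kinetics for the simulator
#'
#' Describes the kinetic model the simulator realizes: a set of independent
#' binding states, each an exponential decay channel with dissociation rate
#' `rates[i]`, entered by a binding event with probability `state_probs[i]`;
#' single-step photobleaching at rate `bleach_rate` per second of illuminated
#' time; and 2-D Brownian motion with coefficient `diffusion` for unbound
#' molecules. `state_probs` are per-event probabilities, i.e. the event
#' spectrum of the simulated kinetics; occupancy (state-spectrum)
#' probabilities follow by dwell-time weighting, see [event_to_state()].
#'
#' @param rates dissociation rates k_i in 1/s, non-negative and distinct.
#' @param state_probs probabilities that a binding event is in state i;
#'   must sum to 1.
#' @param bleach_rate photobleaching rate k_b in 1/s of illuminated time;
#'   the per-frame bleach number is `a = bleach_rate * integration_time`.
#' @param diffusion diffusion coefficient D of unbound molecules, pixel^2/s.
#' @param bound_fraction fraction of visible molecules that are bound.
#' @param labeling_density expected visible spots per nucleus per frame.
#' @param localization_sd localization error of a bound molecule, pixels.
#'
#' @return object of class `ground_truth` (a named list of the above).
#' @examples
#' truth <- ground_truth(rates = c(1 / 910, 0.1), state_probs = c(0.3, 0.7))
#' @export
ground_truth <- function(rates, state_probs,
                         bleach_rate = 1.0,
                         diffusion = 200,
                         bound_fraction = 1,
                         labeling_density = 6,
                         localization_sd = 0.15) {
  if (length(rates) < 1L) stop("at least one bound state is required")
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("dissociation rates must be finite and non-negative")
  if (anyDuplicated(rates)) stop("dissociation rates must be distinct")
  if (length(state_probs) != length(rates))
    stop("state_probs must match rates in length")
  if (any(state_probs < 0) || abs(sum(state_probs) - 1) > 1e-8)
    stop("state_probs must be non-negative and sum to 1")
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  if (diffusion < 0) stop("diffusion must be >= 0")
  if (bound_fraction < 0 || bound_fraction > 1)
    stop("bound_fraction must lie in [0, 1]")
  if (localization_sd < 0) stop("localization_sd must be >= 0")
  structure(list(rates = as.numeric(rates),
                 state_probs = as.numeric(state_probs),
                 bleach_rate = bleach_rate,
                 diffusion = diffusion,
                 bound_fraction = bound_fraction,
                 labeling_density = labeling_density,
                 localization_sd = localization_sd),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth binding kinetics\n")
  for (i in seq_along(x$rates))
    cat(sprintf("  state %d: k = %.4g /s (binding time %s), event prob %.3g\n",
                i, x$rates[i],
                if (x$rates[i] > 0) sprintf("%.3g s", 1 / x$rates[i]) else "Inf",
                x$state_probs[i]))
  cat(sprintf("  bleach rate: %g /s illuminated; D = %g px^2/s; bound fraction %g\n",
              x$bleach_rate, x$diffusion, x$bound_fraction))
  invisible(x)
}

#' Per-frame bleach number of a truth/scheme pair
#'
#' The bleach number `a = bleach_rate * integration_time` is the expected
#' number of bleaching events per illuminated frame; it is shared across
#' time-lapse conditions because the integration time is fixed.
#'
#' @param truth a [ground_truth()].
#' @param scheme an [imaging_scheme()].
#' @return numeric bleach number in 1/frame.
#' @export
bleach_number <- function(truth, scheme) truth$bleach_rate * scheme$integration_time
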