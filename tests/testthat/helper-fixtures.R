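# Shared fixtures: small schemes, truths and noiseless survival builders.

two_cond_scheme <- function() imaging_scheme(c(0.4, 3.2), c(120, 960))

single_state_truth <- function(k = 0.01, bleach_rate = 0) {
  ground_truth(rates = k, state_probs = 1, bleach_rate = bleach_rate)
}

# Noiseless survival distributions evaluated from the closed-form model,
# scaled to a large nominal track count. No movie duration is attached, so
# fits treat them as window-free.
noiseless_survivals <- function(rates, weights, a, taus, n_points = 100,
                                n0 = 1e6) {
  lapply(taus, function(tau) {
    t <- tau * seq_len(n_points)
    s <- model_survival(rates, weights, a = a, tau = tau, t = t)
    structure(list(cycle_time = tau, durations = t, counts = n0 * s,
                   n_tracks = n0, movie_duration = NA_real_),
              class = "survival_dist")
  })
}

# Durations (seconds) drawn from the simulator for one condition, bound
# tracks only, with the per-condition minimum track length applied.
sim_durations <- function(truth, scheme, condition, n, seed,
                          min_len = 2L) {
  sim <- simulate_tracks(truth, scheme, condition, n, seed = seed)
  m <- sim$molecules$n_frames_observed
  m <- m[sim$molecules$state_index > 0 & m >= min_len]
  (m - 1) * scheme$cycle_times[condition]
}

expect_weights_normalized <- function(w) {
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-8)
}
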