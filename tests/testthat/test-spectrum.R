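test_that("model survival evaluates the time-lapse decay law", {
  # no bleaching: decay is condition-independent
  t <- c(0, 5, 10)
  for (tau in c(0.1, 1, 14))
    expect_equal(model_survival(0.05, 1, a = 0, tau = tau, t = t),
                 exp(-0.05 * t))
  # pure bleaching: fixed decay per frame, slower per unit time as the
  # cycle time grows (the time-lapse separation principle)
  n <- 0:20
  expect_equal(model_survival(0, 1, a = 0.05, tau = 0.1, t = n * 0.1),
               exp(-0.05 * n))
  expect_equal(model_survival(0, 1, a = 0.05, tau = 1, t = n * 1),
               exp(-0.05 * n))
  expect_error(model_survival(0.1, 1, a = 0.05, tau = 0, t = 1), "tau")
  expect_error(model_survival(0.1, 1, a = -1, tau = 1, t = 1), "bleach")
})

test_that("one spectrum generates distinct curves across conditions", {
  sch <- construct_scheme("RBPJ")
  curves <- lapply(sch$cycle_times, function(tau)
    model_survival(c(0.001, 0.1), c(0.3, 0.7), a = 0.05, tau = tau,
                   t = seq(0, 30, by = 0.5)))
  for (i in 1:4) for (j in (i + 1):5)
    expect_gt(max(abs(curves[[i]] - curves[[j]])), 1e-3)
})

test_that("event-to-state conversion follows dwell-time weighting", {
  expect_equal(event_to_state(c(0.5, 0.5), c(1.0, 0.1)),
               c(1 / 11, 10 / 11))
  expect_equal(event_to_state(c(0, 1), c(1, 2)), c(0, 1))   # single state
  w <- c(0.2, 0.5, 0.3)
  expect_equal(event_to_state(w, rep(0.4, 3)), w)  # equal rates: s = w
  expect_error(event_to_state(c(0.5, 0.5), c(0, 1)), "occupancy")
  expect_error(event_to_state(c(-0.1, 1.1), c(1, 2)), "non-negative")
})

test_that("a single on-grid exponential is recovered exactly", {
  g <- rate_grid()
  k0 <- g[which.min(abs(g - 0.01))]
  sv <- noiseless_survivals(k0, 1, a = 0, taus = c(0.4, 1.6, 6.4))
  fit <- fit_event_spectrum(sv, g, fix_bleach = 0, capture_correction = FALSE)
  i0 <- which.min(abs(g - k0))
  expect_gte(sum(fit$event_weights[(i0 - 1):(i0 + 1)]), 0.95)
  expect_weights_normalized(fit$event_weights)
  expect_weights_normalized(fit$state_weights)
})

test_that("round trip on noiseless on-grid input has negligible residual", {
  g <- rate_grid()
  idx <- c(which.min(abs(g - 0.005)), which.min(abs(g - 0.5)))
  w_true <- c(0.3, 0.7)
  taus <- c(0.1, 0.4, 1.6, 6.4)
  sv <- noiseless_survivals(g[idx], w_true, a = 0.02, taus = taus)
  # the bleach search tolerance bounds the attainable residual; tighten it
  # so the representation error itself is what gets measured
  fit <- fit_event_spectrum(sv, rate_grid(), capture_correction = FALSE,
                            bleach_tol = 1e-9)
  for (i in seq_along(taus)) {
    t <- sv[[i]]$durations
    recon <- model_survival(fit$rates, fit$event_weights,
                            a = fit$bleach_number, tau = taus[i], t = t)
    recon <- recon / recon[1]
    truth <- sv[[i]]$counts / sv[[i]]$counts[1]
    expect_lt(max(abs(recon - truth)), 1e-6)
  }
})

test_that("two states and the bleach number are recovered from noiseless data", {
  g <- rate_grid()
  idx <- c(which.min(abs(g - 0.005)), which.min(abs(g - 0.5)))
  sv <- noiseless_survivals(g[idx], c(0.3, 0.7), a = 0.02,
                            taus = c(0.1, 0.4, 1.6, 6.4))
  fit <- fit_event_spectrum(sv, g, capture_correction = FALSE)
  expect_lt(abs(fit$bleach_number - 0.02) / 0.02, 0.10)
  step <- g[2] / g[1]
  for (j in 1:2) {
    sel <- g >= g[idx[j]] / step^1.5 & g <= g[idx[j]] * step^1.5
    expect_gt(sum(fit$event_weights[sel]), 0.8 * c(0.3, 0.7)[j])
  }
})

test_that("single-condition fits are refused unless the bleach number is fixed", {
  sv <- noiseless_survivals(0.01, 1, a = 0.05, taus = 1.6)
  expect_error(fit_event_spectrum(sv, rate_grid()), "single")
  fit <- fit_event_spectrum(sv, rate_grid(), fix_bleach = 0.05, capture_correction = FALSE)
  expect_s3_class(fit, "rate_spectrum")
})

test_that("forcing a = 0 on bleached data biases the rate high by ~a/tau", {
  g <- rate_grid()
  k0 <- g[which.min(abs(g - 0.01))]
  a0 <- 0.05; tau <- 1.6
  sv <- noiseless_survivals(k0, 1, a = a0, taus = tau)
  fit <- fit_event_spectrum(sv, g, fix_bleach = 0, capture_correction = FALSE)
  k_hat <- sum(fit$event_weights * g)
  expect_lt(abs(k_hat - (k0 + a0 / tau)) / (k0 + a0 / tau), 0.05)
})

test_that("recovered slowest rate is invariant to bleaching over a 5x range", {
  # the core claim of the time-lapse design: for fixed kinetics, the
  # recovered slowest rate moves by less than one grid step as the bleach
  # number varies 5-fold (multi-condition fits only)
  g <- rate_grid()
  idx <- c(which.min(abs(g - 0.002)), which.min(abs(g - 0.3)))
  taus <- c(0.1, 0.4, 1.6, 6.4, 14)
  k_slow <- vapply(c(0.02, 0.04, 0.06, 0.08, 0.10), function(a0) {
    sv <- noiseless_survivals(g[idx], c(0.4, 0.6), a = a0, taus = taus)
    fit <- fit_event_spectrum(sv, g, capture_correction = FALSE)
    slow <- g < 0.05
    sum((fit$state_weights * g)[slow]) / sum(fit$state_weights[slow])
  }, numeric(1))
  step <- g[2] / g[1]
  expect_lt(max(k_slow) / min(k_slow), step)
})

test_that("rate grids are validated", {
  g <- rate_grid(1e-4, 1e2, 200)
  expect_length(g, 200)
  expect_true(!is.unsorted(g, strictly = TRUE))
  expect_equal(g[1], 1e-4)
  expect_equal(g[200], 1e2)
  expect_error(rate_grid(0, 1), "k_min")
  expect_error(rate_grid(1, 0.1), "k_min")
})
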