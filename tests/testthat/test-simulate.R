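test_that("without decay processes every track runs to the movie end", {
  truth <- ground_truth(rates = 0, state_probs = 1, bleach_rate = 0)
  sch <- two_cond_scheme()
  sim <- simulate_tracks(truth, sch, 1, 200, seed = 1)
  mol <- sim$molecules[sim$molecules$n_frames_observed >= 1, ]
  expect_true(all(mol$end_cause == "movie_end"))
  expect_true(all(mol$first_frame + mol$n_frames_observed - 1L ==
                    sim$n_frames - 1L))
})

test_that("mean observed duration matches the closed-form mean", {
  # one state, no bleaching, movie long enough that window truncation is
  # negligible; closed form for the discretized observation process:
  # E[(frames - 1) * tau] = capture * tau / (exp(k tau) - 1)
  k <- 0.01; tau <- 1.6
  sch <- imaging_scheme(tau, 40000)
  sim <- simulate_tracks(single_state_truth(k), sch, 1, 10000, seed = 42)
  d <- (sim$molecules$n_frames_observed - 1) * tau
  d <- d[sim$molecules$n_frames_observed >= 1]
  capture <- -expm1(-k * tau) / (k * tau)
  exact <- capture * tau / expm1(k * tau)
  expect_lt(abs(mean(d) - exact), 3 * stats::sd(d) / sqrt(length(d)))
  # and the exact mean is itself within ~2% of 1/k_eff = 1/k
  expect_lt(abs(exact - 1 / k) / (1 / k), 0.02)
})

test_that("RBPJ-like run yields one track table per cycle-time condition", {
  sch <- construct_scheme("RBPJ")
  truth <- construct_truth("RBPJ")
  sims <- lapply(seq_len(n_conditions(sch)), function(i)
    simulate_tracks(truth, sch, i, 50, seed = i))
  expect_length(sims, 5)
  expect_equal(vapply(sims, `[[`, numeric(1), "cycle_time"),
               c(0.1, 0.4, 1.6, 6.4, 14))
  for (s in sims)
    expect_true(all(c("molecule_id", "frame", "x", "y") %in%
                      names(s$positions)))
})

test_that("bleached fraction increases monotonically with bleach rate", {
  sch <- imaging_scheme(0.4, 2000)
  frac <- vapply(c(0.2, 1, 3, 8), function(kb) {
    sim <- simulate_tracks(
      ground_truth(0.02, 1, bleach_rate = kb), sch, 1, 4000, seed = 7)
    mean(sim$molecules$end_cause == "bleached")
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("longer dark periods extend observed durations", {
  # the time-lapse principle: bleaching cost per unit time falls as the
  # dark period lengthens, so tracks survive longer in real time
  truth <- ground_truth(0.005, 1, bleach_rate = 1)
  sch <- imaging_scheme(c(0.4, 1.6, 6.4), c(4000, 4000, 4000))
  mean_duration <- vapply(1:3, function(i) {
    sim <- simulate_tracks(truth, sch, i, 4000, seed = 11)
    mean((sim$molecules$n_frames_observed - 1) * sch$cycle_times[i])
  }, numeric(1))
  expect_true(all(diff(mean_duration) > 0))
})

test_that("single-state survival obeys the analytic law within DKW bounds", {
  k <- 0.05; kb <- 1; tau <- 1.6; t_int <- 0.05
  n <- 10000
  sch <- imaging_scheme(tau, 40000, integration_time = t_int)
  sim <- simulate_tracks(ground_truth(k, 1, bleach_rate = kb), sch, 1, n,
                         seed = 3)
  m <- sim$molecules$n_frames_observed
  # P(duration >= n tau) = exp(-k n tau) exp(-kb t_int n), up to the
  # capture factor for the phase between appearance and the first frame
  capture <- -expm1(-k * tau) / (k * tau)
  eps <- sqrt(log(2 / 0.01) / (2 * n))   # DKW 99% band
  for (j in 1:12) {
    emp <- mean(m >= j + 1)
    theo <- capture * exp(-(k * tau + kb * t_int) * j)
    expect_lt(abs(emp - theo), eps + 0.01 * theo)
  }
})

test_that("identical seeds give byte-identical track tables", {
  truth <- construct_truth("RBPJL")
  sch <- construct_scheme("RBPJL")
  s1 <- simulate_tracks(truth, sch, 2, 500, seed = 99)
  s2 <- simulate_tracks(truth, sch, 2, 500, seed = 99)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$molecules, s2$molecules)
})

test_that("degenerate simulator inputs are rejected with clear messages", {
  truth <- single_state_truth()
  sch <- two_cond_scheme()
  expect_error(simulate_tracks(truth, sch, 1, 0), "n_molecules")
  expect_error(simulate_tracks(truth, sch, 7, 10), "condition")
  expect_error(simulate_tracks(truth, sch, 1, 10, field_size = c(0, 10)),
               "zero-area")
  expect_error(ground_truth(numeric(0), numeric(0)), "at least one")
})

test_that("expected bound fraction predicts simulated yields", {
  truth <- construct_truth("RBPJ")
  sch <- construct_scheme("RBPJ")
  for (i in c(1, 5)) {
    p <- expected_bound_fraction(truth, sch, i, min_track_length = 2 + (i == 1))
    sim <- simulate_tracks(truth, sch, i, 20000, seed = i)
    got <- mean(sim$molecules$n_frames_observed >= 2 + (i == 1))
    expect_lt(abs(got - p), 0.015)
  }
})
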