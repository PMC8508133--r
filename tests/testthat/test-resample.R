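make_two_state_durations <- function(seed, n_scale = 1) {
  truth <- ground_truth(c(0.01, 0.5), c(0.5, 0.5), bleach_rate = 0.4)
  sch <- imaging_scheme(c(0.4, 1.6, 6.4), c(120, 480, 960))
  durs <- lapply(1:3, function(i)
    sim_durations(truth, sch, i, round(1500 * n_scale), seed = seed + i))
  list(durations = durs, cycle_times = sch$cycle_times,
       movie_durations = sch$movie_durations, truth = truth)
}

test_that("resampling defaults follow the published error model", {
  expect_equal(formals(resample_spectra)$n_resamples, 499)
  expect_equal(formals(resample_spectra)$fraction, 0.8)
})

test_that("degenerate data give identical resamples with zero spread", {
  durs <- list(rep(1.6, 50), rep(6.4, 40))
  rs <- resample_spectra(durs, c(1.6, 6.4), rate_grid(1e-3, 10, 80),
                         n_resamples = 15, seed = 1)
  expect_equal(nrow(rs$state_weights), 15L)
  expect_true(all(apply(rs$state_weights, 2, stats::sd) == 0))
  st <- slowest_cluster_stats(rs)
  expect_equal(st$sd_rate, 0)
})

test_that("resampling is deterministic given a seed and tracks subsets", {
  d <- make_two_state_durations(5)
  g <- rate_grid(1e-3, 10, 60)
  rs1 <- resample_spectra(d$durations, d$cycle_times, g,
                          movie_durations = d$movie_durations,
                          n_resamples = 8, seed = 42)
  rs2 <- resample_spectra(d$durations, d$cycle_times, g,
                          movie_durations = d$movie_durations,
                          n_resamples = 8, seed = 42)
  expect_identical(rs1$state_weights, rs2$state_weights)
  expect_identical(rs1$bleach_numbers, rs2$bleach_numbers)
  expect_error(resample_spectra(list(numeric(3)), 1.6, fraction = 0.1),
               "too few tracks")
})

test_that("slowest-cluster statistics reduce correctly on point masses", {
  g <- rate_grid(1e-4, 1, 100)
  i0 <- which.min(abs(g - 0.002))
  one <- matrix(0, 5, 100); one[, i0] <- 1
  rs <- structure(list(rates = g, state_weights = one, event_weights = one,
                       merged_state = colMeans(one),
                       merged_event = colMeans(one),
                       max_span = 1400, n_resamples = 5, fraction = 0.8),
                  class = "resampled_spectra")
  st <- slowest_cluster_stats(rs)
  expect_equal(st$mean_rate, g[i0])
  expect_equal(st$sd_rate, 0)
  expect_equal(st$binding_time, 1 / g[i0])
})

test_that("cluster statistics match a hand-computed weighted mean", {
  g <- rate_grid(1e-4, 1, 200)
  i1 <- which.min(abs(g - 0.001)); i2 <- which.min(abs(g - 0.00125))
  w <- matrix(0, 2, 200); w[1, i1] <- 1; w[2, i2] <- 1
  rs <- structure(list(rates = g, state_weights = w, event_weights = w,
                       merged_state = colMeans(w) / sum(colMeans(w)),
                       merged_event = colMeans(w) / sum(colMeans(w)),
                       max_span = 1400, n_resamples = 2, fraction = 0.8),
                  class = "resampled_spectra")
  st <- slowest_cluster_stats(rs, borders = c(5e-4, 5e-3))
  expect_equal(st$mean_rate, mean(c(g[i1], g[i2])))
  expect_equal(st$binding_time, 1 / mean(c(g[i1], g[i2])),
               tolerance = 1e-12)
  # ~888.9 s for exact rates 0.001 and 0.00125; grid snapping keeps it close
  expect_lt(abs(st$binding_time - 888.9), 35)
  expect_match(format_binding_time(st), "mean ± s.d. from resampling")
})

test_that("cluster statistics are invariant to widening into empty regions", {
  d <- make_two_state_durations(9)
  g <- rate_grid()
  rs <- resample_spectra(d$durations, d$cycle_times, g,
                         movie_durations = d$movie_durations,
                         n_resamples = 12, seed = 3)
  b <- auto_borders(rs)
  st0 <- slowest_cluster_stats(rs, b)
  # widen both borders into regions the merged spectrum leaves empty
  wider <- c(b[1] * 0.9, b[2] * 1.05)
  sel_extra <- g >= wider[1] & g <= wider[2] &
    !(g >= b[1] & g <= b[2])
  skip_if(any(rs$merged_event[sel_extra] > 0))
  st1 <- slowest_cluster_stats(rs, wider)
  expect_equal(st1$mean_rate, st0$mean_rate)
  expect_equal(st1$sd_rate, st0$sd_rate)
})

test_that("errors name impossible borders", {
  d <- make_two_state_durations(13)
  rs <- resample_spectra(d$durations, d$cycle_times, rate_grid(1e-3, 10, 60),
                         movie_durations = d$movie_durations,
                         n_resamples = 6, seed = 11)
  expect_error(slowest_cluster_stats(rs, borders = c(2e-3, 1e-3)), "k_low")
  expect_error(slowest_cluster_stats(rs, borders = c(1e-7, 2e-7)),
               "no merged spectrum mass")
})

test_that("resampling spread shrinks with data volume roughly as 1/sqrt(n)", {
  g <- rate_grid(1e-3, 10, 80)
  sds <- vapply(c(1, 4), function(ns) {
    d <- make_two_state_durations(17, n_scale = ns)
    rs <- resample_spectra(d$durations, d$cycle_times, g,
                           movie_durations = d$movie_durations,
                           n_resamples = 40, seed = 19)
    slowest_cluster_stats(rs)$sd_rate
  }, numeric(1))
  expect_gt(sds[1] / sds[2], 1.2)
  expect_lt(sds[1] / sds[2], 3.6)
})
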