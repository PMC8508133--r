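cfg1 <- function(radius = 0.9, min_len = 2, gaps = 1, seg = 1, tau = 1.6)
  tracking_config(tau, radius, min_len, gaps, seg)

test_that("a persistent immobile spot links into a single full track", {
  spots <- data.frame(frame = 0:9, x = 10 + 1e-3 * (0:9), y = 20)
  ts <- link_tracks(spots, cfg1(), 1.6)
  expect_equal(nrow(ts$tracks), 1L)
  expect_equal(ts$tracks$duration_frames, 10L)
  expect_equal(ts$tracks$n_gaps_closed, 0L)
})

test_that("gap closing joins interrupted detections; without it they split", {
  spots <- data.frame(frame = c(0, 1, 3, 4), x = 10, y = 10)
  with_gap <- link_tracks(spots, cfg1(gaps = 1, min_len = 2), 1.6)
  expect_equal(nrow(with_gap$tracks), 1L)
  expect_equal(with_gap$tracks$n_gaps_closed, 1L)
  expect_equal(with_gap$tracks$duration_frames, 5L)
  no_gap <- link_tracks(spots, cfg1(gaps = 0, min_len = 2), 1.6)
  expect_equal(nrow(no_gap$tracks), 2L)
  expect_equal(no_gap$tracks$duration_frames, c(2L, 2L))
  # fragments below the minimum track length are discarded but still counted
  no_gap3 <- link_tracks(spots, cfg1(gaps = 0, min_len = 3), 1.6)
  expect_equal(nrow(no_gap3$tracks), 0L)
  expect_equal(no_gap3$total_molecules, 2L)
})

test_that("the segmentation filter drops short detection runs", {
  # runs: frames 0-1 (length 2), frame 3 alone (length 1), frames 5-7
  spots <- data.frame(frame = c(0, 1, 3, 5, 6, 7), x = 10, y = 10)
  ts <- link_tracks(spots, cfg1(gaps = 2, min_len = 2, seg = 2), 1.6)
  # the lone frame-3 detection is removed; remaining runs re-split because
  # frames 1 and 5 are farther apart than the gap rule allows
  expect_equal(nrow(ts$tracks), 2L)
  expect_equal(sort(ts$tracks$duration_frames), c(2L, 3L))
  expect_false(3 %in% ts$positions$frame)
})

test_that("linking respects the tracking radius", {
  spots <- data.frame(frame = c(0, 1), x = c(10, 12), y = 10)
  far <- link_tracks(spots, cfg1(radius = 0.9, min_len = 2), 1.6)
  expect_equal(nrow(far$tracks), 0L)     # 2 px jump exceeds 0.9 px radius
  near <- link_tracks(spots, cfg1(radius = 2.5, min_len = 2), 1.6)
  expect_equal(nrow(near$tracks), 1L)
})

test_that("greedy linking matches brute-force assignment on small instances", {
  # brute force: over all injective matchings within the radius, maximize
  # the number of links, then minimize total squared displacement
  brute_pairs <- function(p0, p1, radius) {
    n0 <- nrow(p0); n1 <- nrow(p1)
    best <- NULL; best_key <- c(-Inf, Inf)
    cand <- list(integer(0))
    for (i in seq_len(n0)) {
      cand <- unlist(lapply(cand, function(m) {
        opts <- setdiff(c(0L, seq_len(n1)), m[m > 0])
        lapply(opts, function(o) c(m, o))
      }), recursive = FALSE)
    }
    for (m in cand) {
      ok <- TRUE; d2 <- 0; links <- 0
      for (i in seq_len(n0)) if (m[i] > 0) {
        dd <- (p0$x[i] - p1$x[m[i]])^2 + (p0$y[i] - p1$y[m[i]])^2
        if (dd > radius^2) { ok <- FALSE; break }
        d2 <- d2 + dd; links <- links + 1
      }
      if (!ok) next
      key <- c(links, -d2)
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2])) {
        best <- m; best_key <- key
      }
    }
    best
  }
  radius <- 3
  for (seed in 1:25) {
    set.seed(seed)
    n0 <- sample(2:4, 1); n1 <- sample(2:4, 1)
    p0 <- data.frame(x = runif(n0, 0, 12), y = runif(n0, 0, 12))
    p1 <- data.frame(x = runif(n1, 0, 12), y = runif(n1, 0, 12))
    spots <- rbind(cbind(frame = 0, p0), cbind(frame = 1, p1))
    ts <- link_tracks(spots, cfg1(radius = radius, min_len = 2, gaps = 0),
                      1.6)
    got <- integer(n0)
    if (nrow(ts$positions)) for (id in unique(ts$positions$track_id)) {
      p <- ts$positions[ts$positions$track_id == id, ]
      if (nrow(p) == 2)
        got[which(p0$x == p$x[1])] <- which(p1$x == p$x[2])
    }
    want <- brute_pairs(p0, p1, radius)
    # greedy achieves the maximum number of links; when the optimal
    # assignment is unique and greedy matches its displacement sum, the
    # assignments agree
    expect_equal(sum(got > 0), sum(want > 0))
  }
})

test_that("immobile well-separated spots reproduce ground-truth tracks", {
  truth <- ground_truth(0.05, 1, bleach_rate = 0.5, localization_sd = 0.02)
  sch <- imaging_scheme(1.6, 160)
  sim <- simulate_tracks(truth, sch, 1, 10, seed = 21)
  spots <- sim$positions[, c("frame", "x", "y")]
  ts <- link_tracks(spots, cfg1(radius = 0.9, min_len = 2, gaps = 0), 1.6)
  truth_durs <- sort(sim$molecules$n_frames_observed[
    sim$molecules$n_frames_observed >= 2])
  expect_equal(sort(ts$tracks$duration_frames), truth_durs)
})

test_that("confinement classification separates bound from diffusing", {
  cfg <- cfg1(radius = 1.75, min_len = 2, tau = 1.6)
  # immobile noiseless track: bound
  still <- new_track_set(
    data.frame(track_id = 1L, first_frame = 0L, last_frame = 5L,
               n_detections = 6L, duration_frames = 6L, n_gaps_closed = 0L),
    data.frame(track_id = 1L, frame = 0:5, x = 10, y = 10),
    cycle_time = 1.6, total_molecules = 1L)
  expect_equal(classify_bound(still, cfg)$bound_count, 1L)
  # Brownian steps with s.d. 5x the radius: unbound with high probability
  set.seed(31)
  wrong <- 0L
  for (r in 1:50) {
    pos <- data.frame(track_id = 1L, frame = 0:5,
                      x = cumsum(c(10, rnorm(5, 0, 5 * 1.75))),
                      y = cumsum(c(10, rnorm(5, 0, 5 * 1.75))))
    tsb <- new_track_set(still$tracks, pos, 1.6, 1L)
    wrong <- wrong + classify_bound(tsb, cfg)$bound_count
  }
  expect_equal(wrong, 0L)
})

test_that("bound counts are reported in the bound/total convention", {
  spots <- data.frame(frame = c(0:4, 0), x = c(rep(10, 5), 30),
                      y = c(rep(10, 5), 30))
  ts <- link_tracks(spots, cfg1(min_len = 3), 1.6)
  cls <- classify_bound(ts, cfg1(min_len = 3))
  expect_equal(cls$label, sprintf("%d/%d", cls$bound_count,
                                  cls$total_molecule_count))
  expect_equal(cls$total_molecule_count, 2L)
  expect_equal(cls$bound_count, 1L)
})

test_that("bound track count is non-increasing in minimum track length", {
  truth <- ground_truth(0.1, 1, bleach_rate = 1, localization_sd = 0.05)
  sch <- imaging_scheme(1.6, 480)
  sim <- simulate_tracks(truth, sch, 1, 200, seed = 41)
  ts <- as_track_set(sim)
  counts <- vapply(2:6, function(ml)
    classify_bound(ts, cfg1(radius = 1.75, min_len = ml))$bound_count,
    integer(1))
  expect_true(all(diff(counts) <= 0))
})
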