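#' Logarithmic grid of candidate dissociation rates
#'
#' The spectrum is inferred on a fixed grid of candidate rates. The default
#' 200 log-spaced points over \[1e-4, 1e2\] 1/s bracket both binding times of
#' many minutes and frame-rate-limited fast dissociation; the grid spacing
#' (about 7% between neighbours) sets the rate resolution of the method.
#'
#' @param k_min,k_max grid bounds in 1/s; `k_min` must be > 0.
#' @param n_points number of grid points.
#' @return numeric vector of strictly increasing rates.
#' @export
rate_grid <- function(k_min = 1e-4, k_max = 1e2, n_points = 200) {
  if (k_min <= 0 || k_max <= k_min) stop("require 0 < k_min < k_max")
  if (n_points < 2) stop("n_points must be >= 2")
  exp(seq(log(k_min), log(k_max), length.out = n_points))
}

#' Model survival function of a rate spectrum under time-lapse imaging
#'
#' Under a time-lapse condition with frame cycle time `tau`, a binding state
#' with dissociation rate k decays with the effective rate `k + a / tau`,
#' where `a` is the per-frame bleach number: the bleaching contribution per
#' unit time shrinks as the dark period lengthens, which is what lets a
#' global fit over several conditions separate bleaching from dissociation.
#'
#' @param rates grid of dissociation rates, 1/s.
#' @param weights event weights on the grid (non-negative).
#' @param a bleach number, 1/frame (>= 0).
#' @param tau frame cycle time, s (> 0).
#' @param t times at which to evaluate, s (multiples of `tau` correspond to
#'   acquired frames).
#' @return numeric vector `sum_i w_i * exp(-(k_i + a/tau) * t)`.
#' @examples
#' model_survival(0.05, 1, a = 0, tau = 0.1, t = c(0, 10, 20))
#' @export
model_survival <- function(rates, weights, a, tau, t) {
  if (tau <= 0) stop("tau must be > 0")
  if (a < 0) stop("bleach number must be >= 0")
  as.numeric(exp(-outer(t, rates + a / tau)) %*% weights)
}

#' Convert an event spectrum to a state spectrum
#'
#' The event spectrum gives how frequently dissociation events from each
#' state occur; dividing by the rate weights each state by its mean dwell
#' time, turning event frequency into the probability of finding a molecule
#' in that state at a random time snapshot (the state spectrum, which is
#' what gets reported).
#'
#' @param weights normalized non-negative event weights.
#' @param rates matching dissociation rates; every rate carrying weight must
#'   be > 0 (a zero rate would mean infinite occupancy).
#' @return state weights `s_i = (w_i / k_i) / sum_j (w_j / k_j)`.
#' @examples
#' event_to_state(c(0.5, 0.5), c(1, 0.1))  # c(1, 10) / 11
#' @export
event_to_state <- function(weights, rates) {
  stopifnot(length(weights) == length(rates))
  if (any(weights < 0)) stop("event weights must be non-negative")
  if (any(rates == 0 & weights > 0))
    stop("zero dissociation rate with positive weight: occupancy undefined")
  s <- ifelse(weights > 0, weights / rates, 0)
  tot <- sum(s)
  if (tot == 0) return(s)
  s / tot
}

#' Fit a dissociation-rate spectrum to survival distributions (global fit)
#'
#' Inverse Laplace inference of the dissociation-rate spectrum: finds
#' non-negative weights on a fixed rate grid, together with one shared
#' per-frame bleach number, that jointly reproduce the survival-time
#' distributions of all time-lapse conditions. The bleach number is found
#' by a 1-D minimization ([stats::optimize()], tolerance `bleach_tol`) of
#' the residual profile; for each candidate bleach number the grid weights
#' are obtained by non-negative least squares ([nnls_gram()]), alternated
#' with a closed-form update of one free amplitude per condition (the
#' per-condition track yield is not comparable across conditions, and the
#' distributions start at `min_track_length - 1` cycles rather than zero).
#' Sparsity of the spectrum emerges from the non-negativity constraint;
#' there is no smoothness penalty, and uncertainty comes from resampling
#' (see [resample_spectra()]).
#'
#' Two objectives are available. The default, `"chisq"`, fits the
#' per-duration count histogram (the decrements of the survival function)
#' with inverse-variance (Poisson) bin weights `1 / max(count, 1)` over the
#' full duration lattice of each condition, including empty bins: these
#' counts are nearly independent, so the weighted sum of squares
#' approximates the multinomial likelihood, and the sparse tail of the data
#' - the only part informative about the slowest rates - constrains the fit
#' with its proper statistical weight. `"lsq"` is the plain unweighted sum
#' of squares between normalized empirical and modeled survival functions
#' (each condition's curve normalized to 1 at its first point and weighted
#' equally); it is kept for comparison and for noiseless closed-form
#' inputs, but on finite data it is much less efficient for slow rates.
#'
#' @param survivals list of `survival_dist` objects; at least two distinct
#'   cycle times are required unless `fix_bleach` is given, because a single
#'   condition cannot separate bleaching from slow dissociation.
#' @param grid rate grid from [rate_grid()].
#' @param bleach_range search interval for the bleach number, 1/frame.
#' @param bleach_tol tolerance of the 1-D bleach-number search.
#' @param fix_bleach fix the bleach number instead of fitting it (use 0 for
#'   bleaching-free data; also the explicit override that permits a
#'   single-condition fit).
#' @param objective `"chisq"` (default) or `"lsq"`, see Details.
#' @param pearson for the `"chisq"` objective, refit once with
#'   inverse-variance weights taken from the model-predicted bin counts of a
#'   first pass (default). Pure observed-count (Neyman) weights mis-weight
#'   empty and near-empty tail bins, which biases the bleach number high and
#'   the slowest rates low; the Pearson pass removes this.
#' @param expected_counts optional externally supplied expected bin counts
#'   (the `expected_bins` element of a previous fit on the same data, e.g.
#'   the full-data fit during resampling): a list, per condition, of
#'   `cycle_time`, `mm` (track lengths in frames) and `E` (expected counts).
#'   When given, they define the bin weights directly and no Pearson pass is
#'   run; the overall scale per condition is irrelevant.
#' @param max_alternations cap on amplitude/weights alternations per
#'   bleach-number evaluation.
#' @param window_correction model the finite observation window (default):
#'   where a distribution carries its movie duration, the expected number
#'   of tracks spanning `t/tau` cycles is additionally proportional to the
#'   number of admissible start frames, `n_frames - 1 - t/tau`. Without
#'   this factor, tracks cut short by the end of the movie bias slow rates
#'   high whenever movies are not much longer than the slowest dwell time.
#' @param capture_correction scale each candidate rate's contribution by
#'   the probability that a binding event starting at a random phase within
#'   a frame cycle is captured at its first acquired frame,
#'   `(1 - exp(-k tau)) / (k tau)` (default). This matters for states
#'   dissociating within about one cycle time; disable it for idealized
#'   inputs generated from the continuous-time decay law.
#' @return object of class `rate_spectrum`: list with `rates` (the grid),
#'   `event_weights` (normalized), `state_weights`, `bleach_number`,
#'   `residual` (weighted sum of squares), `amplitudes` (per condition),
#'   `cycle_times`, and `fitted` (per condition: `t`, empirical normalized
#'   `survival`, normalized model survival `model`), suitable for
#'   overlaying model curves on the data.
#' @examples
#' g <- rate_grid(1e-3, 10, 60)
#' tau <- c(0.4, 3.2)
#' sv <- lapply(tau, function(tt) {
#'   t <- tt * (1:50)
#'   build_survival(rep(t, round(1000 * exp(-0.05 * t))), cycle_time = tt)
#' })
#' fit <- fit_event_spectrum(sv, g, fix_bleach = 0)
#' g[which.max(fit$event_weights)]  # near 0.05
#' @export
fit_event_spectrum <- function(survivals, grid = rate_grid(),
                               bleach_range = c(0, 2), bleach_tol = 1e-4,
                               fix_bleach = NULL,
                               objective = c("chisq", "lsq"),
                               pearson = TRUE, expected_counts = NULL,
                               max_alternations = 30,
                               window_correction = TRUE,
                               capture_correction = TRUE) {
  objective <- match.arg(objective)
  if (inherits(survivals, "survival_dist")) survivals <- list(survivals)
  survivals <- survivals[vapply(survivals, function(s) s$n_tracks > 0,
                                logical(1))]
  if (!length(survivals)) stop("no non-empty survival distributions")
  taus <- vapply(survivals, `[[`, numeric(1), "cycle_time")
  if (length(unique(taus)) < 2 && is.null(fix_bleach))
    stop(paste("a single time-lapse condition cannot separate bleaching",
               "from slow dissociation; supply >= 2 conditions or set",
               "fix_bleach explicitly"))

  conds <- lapply(survivals, function(s) {
    tau <- s$cycle_time
    md <- if (window_correction) (s$movie_duration %||% NA_real_) else NA_real_
    nf <- if (is.finite(md)) floor(md / tau) else NA_integer_
    m_obs <- round(s$durations / tau) + 1L     # track lengths in frames
    # capture factor: probability that a binding event starting at a random
    # phase within a frame cycle is still bound at its first acquired
    # frame, (1 - exp(-k tau)) / (k tau); a per-rate, per-condition scale
    capture <- if (capture_correction) -expm1(-grid * tau) / (grid * tau) else
      rep(1, length(grid))
    if (objective == "chisq") {
      m_hi <- if (!is.na(nf)) max(nf - 1L, max(m_obs)) else max(m_obs)
      mm <- seq.int(min(m_obs), m_hi)
      cnt <- numeric(length(mm))
      cnt[match(m_obs, mm)] <- -diff(c(s$counts, 0))  # tracks of exactly m frames
      # admissible start frames for a track of m frames: nf - m
      g_all <- if (!is.na(nf)) pmax(nf - c(mm, m_hi + 1L), 0) else
        rep(1, length(mm) + 1L)
      # the final bin is an overflow bin (all tracks of >= m_hi frames), so
      # distributions truncated before the longest observable duration keep
      # their censored lump consistent with the model
      g_all[length(g_all)] <- 0
      list(tau = tau, mm = mm, y = cnt, wpt = 1 / pmax(cnt, 1),
           g_head = g_all[-length(g_all)], g_tail = g_all[-1],
           zk = exp(-grid * tau),
           B = t(t(exp(-outer(mm - 1, grid * tau))) * capture),
           s_t = s$durations, s_counts = s$counts)
    } else {
      win <- if (!is.na(nf)) pmax(nf - m_obs, 1e-12) else rep(1, length(m_obs))
      list(tau = tau, mm = m_obs, y = s$counts / s$counts[1],
           wpt = rep(1 / length(m_obs), length(m_obs)),
           win = win / win[1],
           B = t(t(exp(-outer(m_obs - 1, grid * tau))) * capture),
           s_t = s$durations, s_counts = s$counts)
    }
  })

  design <- function(cond, a) {
    ra <- exp(-a * (cond$mm - 1))
    if (objective == "chisq") {
      # expected count in bin m: g(m) z^(m-1) - g(m+1) z^m  per unit weight
      P1 <- cond$B * ra
      P2 <- t(t(P1) * cond$zk) * exp(-a)
      cond$g_head * P1 - cond$g_tail * P2
    } else {
      cond$B * (cond$win * ra)
    }
  }

  solve_at <- function(a) {
    C <- length(conds)
    As <- vector("list", C); Gs <- vector("list", C); hs <- vector("list", C)
    for (i in seq_len(C)) {
      A <- design(conds[[i]], a)
      As[[i]] <- A
      wA <- A * conds[[i]]$wpt
      Gs[[i]] <- crossprod(wA, A)
      hs[[i]] <- as.numeric(crossprod(wA, conds[[i]]$y))
    }
    alphas <- rep(1, C)
    w <- numeric(length(grid))
    models <- vector("list", C)
    for (it in seq_len(max_alternations)) {
      G <- Reduce(`+`, Map(function(g, al) al^2 * g, Gs, alphas))
      h <- Reduce(`+`, Map(function(hh, al) al * hh, hs, alphas))
      w <- nnls_gram(G, h, x0 = if (it > 1L) w)
      if (all(w == 0)) break
      new_al <- alphas
      for (i in seq_len(C)) {
        m <- as.numeric(As[[i]] %*% w)
        models[[i]] <- m
        mm2 <- sum(conds[[i]]$wpt * m * m)
        new_al[i] <- if (mm2 > 0)
          sum(conds[[i]]$wpt * conds[[i]]$y * m) / mm2 else 0
      }
      done <- max(abs(new_al - alphas)) < 1e-7 * max(abs(new_al), 1)
      alphas <- new_al
      if (done) break
    }
    resid <- 0
    for (i in seq_len(C)) {
      m <- if (all(w == 0)) rep(0, length(conds[[i]]$y)) else
        as.numeric(As[[i]] %*% w)
      models[[i]] <- alphas[i] * m
      resid <- resid + sum(conds[[i]]$wpt * (conds[[i]]$y - models[[i]])^2)
    }
    list(w = w, alphas = alphas, resid = resid, models = models)
  }

  if (!is.null(fix_bleach) && fix_bleach < 0)
    stop("bleach number must be >= 0")
  run_round <- function() {
    a_hat <- if (is.null(fix_bleach)) {
      stats::optimize(function(a) solve_at(a)$resid,
                      interval = bleach_range, tol = bleach_tol)$minimum
    } else fix_bleach
    list(a = a_hat, sol = solve_at(a_hat))
  }

  if (objective == "chisq") {
    if (!is.null(expected_counts)) {
      # weights supplied by a previous fit on (a superset of) the same data
      for (i in seq_along(conds)) {
        ec <- Filter(function(e)
          abs(e$cycle_time - conds[[i]]$tau) < 1e-9, expected_counts)
        if (length(ec) != 1L)
          stop(sprintf("expected_counts has no entry for cycle time %g s",
                       conds[[i]]$tau))
        e_at <- ec[[1]]$E[match(conds[[i]]$mm, ec[[1]]$mm)]
        conds[[i]]$wpt <- 1 / pmax(ifelse(is.na(e_at), 0, e_at), 0.1)
      }
    } else if (pearson) {
      # Pearson pass: weights from model-predicted counts of a first fit
      r0 <- run_round()
      for (i in seq_along(conds))
        conds[[i]]$wpt <- 1 / pmax(r0$sol$models[[i]], 0.1)
    }
  }
  fin <- run_round()
  a_hat <- fin$a
  sol <- fin$sol
  total_w <- sum(sol$w)
  event_weights <- if (total_w > 0) sol$w / total_w else sol$w
  fitted <- lapply(seq_along(conds), function(i) {
    cd <- conds[[i]]
    if (objective == "chisq") {
      cum <- rev(cumsum(rev(sol$models[[i]])))
      model <- cum[match(round(cd$s_t / cd$tau) + 1L, cd$mm)]
      model <- model / model[1]
    } else {
      model <- sol$models[[i]]
    }
    list(cycle_time = taus[i], t = cd$s_t,
         survival = cd$s_counts / cd$s_counts[1], model = model)
  })
  expected_bins <- if (objective == "chisq") {
    lapply(seq_along(conds), function(i)
      list(cycle_time = conds[[i]]$tau, mm = conds[[i]]$mm,
           E = sol$models[[i]]))
  } else NULL
  structure(list(rates = grid, event_weights = event_weights,
                 state_weights = event_to_state(event_weights, grid),
                 bleach_number = a_hat, residual = sol$resid,
                 amplitudes = sol$alphas, cycle_times = taus,
                 fitted = fitted, expected_bins = expected_bins),
            class = "rate_spectrum")
}

#' @export
print.rate_spectrum <- function(x, ...) {
  cat("Dissociation-rate spectrum (global inverse Laplace fit)\n")
  cat(sprintf("  conditions: %s s; bleach number %.4g /frame; residual %.4g\n",
              paste(x$cycle_times, collapse = "/"), x$bleach_number,
              x$residual))
  nz <- which(x$event_weights > 1e-6)
  for (i in nz)
    cat(sprintf("  k = %.4g /s (%.4g s): event %.3f, state %.3f\n",
                x$rates[i], 1 / x$rates[i], x$event_weights[i],
                x$state_weights[i]))
  invisible(x)
}

#' Plot survival distributions with fitted model curves
#'
#' Overlays the fitted model survival functions on the empirical
#' distributions, one curve per time-lapse condition, on a log survival
#' axis.
#'
#' @param x a `rate_spectrum` from [fit_event_spectrum()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.rate_spectrum <- function(x, ...) {
  cols <- grDevices::hcl.colors(length(x$fitted), "Dark 2")
  all_t <- unlist(lapply(x$fitted, `[[`, "t"))
  all_s <- unlist(lapply(x$fitted, `[[`, "survival"))
  graphics::plot(range(all_t), range(all_s[all_s > 0]), type = "n",
                 log = "xy", xlab = "survival time (s)",
                 ylab = "normalized survival", ...)
  for (i in seq_along(x$fitted)) {
    f <- x$fitted[[i]]
    graphics::points(f$t, f$survival, col = cols[i], pch = 16, cex = 0.4)
    graphics::lines(f$t, f$model, col = "black")
  }
  graphics::legend("topright", legend = sprintf("%g s", x$cycle_times),
                   col = cols, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Plot a dissociation-rate spectrum
#'
#' Stem plot of spectrum weights over the (logarithmic) rate grid.
#' @param spectrum a `rate_spectrum`, or a list with `rates` and weights.
#' @param which `"state"` (default, the reported spectrum) or `"event"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_spectrum <- function(spectrum, which = c("state", "event"), ...) {
  which <- match.arg(which)
  w <- if (which == "state") spectrum$state_weights else spectrum$event_weights
  graphics::plot(spectrum$rates, w, type = "h", log = "x",
                 xlab = "dissociation rate (1/s)",
                 ylab = sprintf("%s weight", which), ...)
  invisible(spectrum)
}
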