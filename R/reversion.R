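# Long-term reversion detection and rise-time fitting.
#
# A long-term reversion is a sustained change of travel direction: the
# cargo backtracks at least `min_back` (250 nm) for more than `min_dur`
# (1 s). In loosely coupled systems the approach to the reversal point is
# wave-shaped: the cargo slows down along a saturating exponential
# x(t) = A (1 - exp(-t / t_r)) + c whose time constant t_r characterizes
# the gradually balancing tug-of-war that precedes the reversal.

#' Detect long-term direction reversions
#'
#' Locates extrema of the smoothed path where the subsequent
#' opposite-direction excursion reaches `min_back` nm and lasts longer
#' than `min_dur` s. Events are non-overlapping by construction; the
#' reversal index is refined to the raw-path extremum near the smoothed
#' one.
#'
#' @param traj a `cargo_trajectory` or (t, x) data frame.
#' @param min_back minimum backtrack displacement (nm).
#' @param min_dur minimum backtrack duration (s).
#' @param smooth_window moving-average window (s) used to suppress thermal
#'   jitter below the step scale before extremum detection.
#' @return list of unfitted `reversion_event` objects, each with the
#'   reversal index/time/position, the pre-reversal window start and the
#'   pre-reversal direction.
#' @export
detect_reversions <- function(traj, min_back = 250, min_dur = 1,
                              smooth_window = 0.05) {
  tx <- traj_tx(traj)
  n <- length(tx$x)
  if (n < 3) return(list())
  dt_s <- stats::median(diff(tx$t))
  w <- max(1L, round(smooth_window / dt_s))
  xs <- moving_average(tx$x, w)
  tp <- zigzag_points(xs, min_back)
  if (length(tp) < 3) return(list())
  events <- list()
  # each interior turning point tp[k] is a candidate reversal; its incoming
  # leg is [tp[k-1], tp[k]] and outgoing leg [tp[k], tp[k+1]]
  for (k in seq_along(tp)) {
    if (k == 1 || k == length(tp)) next
    i_rev <- tp[k]; i_next <- tp[k + 1]
    back_disp <- xs[i_next] - xs[i_rev]
    back_dur <- tx$t[i_next] - tx$t[i_rev]
    pre_dir <- sign(xs[i_rev] - xs[tp[k - 1]])
    if (abs(back_disp) < min_back || back_dur <= min_dur) next
    if (sign(back_disp) == pre_dir) next
    # refine reversal to the raw-path extremum near the smoothed one
    lo <- max(1L, i_rev - w); hi <- min(n, i_rev + w)
    i_raw <- if (pre_dir > 0) lo - 1L + which.max(tx$x[lo:hi])
             else lo - 1L + which.min(tx$x[lo:hi])
    events[[length(events) + 1]] <- structure(
      list(i_rev = i_raw, t_rev = tx$t[i_raw], x_rev = tx$x[i_raw],
           i_pre_start = tp[k - 1], direction = pre_dir,
           back_displacement = back_disp, back_duration = back_dur,
           fitted = FALSE),
      class = "reversion_event")
  }
  events
}

#' Fit the reversion rise time
#'
#' Fits the pre-reversal approach with a constant-velocity phase that
#' rolls off into the saturating exponential
#' `x(t) = A (1 - exp(-(t - t0)/t_r)) + c` for `t > t0`, continuous in
#' value and slope at the onset `t0` (the linear phase has slope
#' `A / t_r`). The onset -- the point where the position-time dependence
#' deviates from linearity -- is a free parameter of the fit; it is
#' initialized at the last sample still predicted by the
#' constant-velocity fit of the early approach within a
#' `band_sigma`-sigma residual band.
#'
#' @param event a `reversion_event` from [detect_reversions()].
#' @param traj the trajectory the event was detected in.
#' @param band_sigma width of the linearity band in early-window sigmas.
#' @param early_frac fraction of the approach used for the linear fit.
#' @param approach_window length (s) of the pre-reversal approach that is
#'   examined; the slowing-down phase lives in the last second before
#'   the reversal, and restricting the window keeps the linear phase of
#'   the model local (velocity fluctuations over a long processive run
#'   otherwise leak into the fit and inflate the recovered time
#'   constant).
#' @param min_fit_samples minimum samples in the approach window.
#' @return the event with `fitted = TRUE` and fields `A` (nm), `t_r_ms`,
#'   `offset` (nm), `onset_index`, `resid_sd`; or `fitted = FALSE` with a
#'   `flag` explaining why (too-short window, no slowing-down phase, an
#'   unidentifiable time constant longer than the fitted window, or a
#'   non-convergent fit).
#' @export
fit_rise_time <- function(event, traj, band_sigma = 3, early_frac = 0.5,
                          approach_window = 1, min_fit_samples = 20) {
  tx <- traj_tx(traj)
  i0 <- event$i_pre_start; i1 <- event$i_rev
  flag <- function(ev, why) { ev$fitted <- FALSE; ev$flag <- why; ev }
  if (i1 - i0 + 1 < min_fit_samples) return(flag(event, "window_too_short"))
  dt_s <- stats::median(diff(tx$t))
  i0 <- max(i0, i1 - round(approach_window / dt_s))
  tt <- tx$t[i0:i1]; xx <- tx$x[i0:i1]
  n <- length(tt)
  n_early <- max(min_fit_samples, floor(early_frac * n))
  if (n_early >= n) return(flag(event, "no_slowing_phase"))
  fit_lin <- stats::lm.fit(cbind(1, tt[1:n_early]), xx[1:n_early])
  sig <- stats::sd(fit_lin$residuals)
  if (!is.finite(sig) || sig == 0) sig <- 1e-6
  pred <- fit_lin$coefficients[1] + fit_lin$coefficients[2] * tt
  dev <- abs(xx - pred) > band_sigma * sig
  # initialization of the onset: last sustained stay within the band
  run <- 5L
  sustained <- which(vapply(seq_len(n - run + 1),
                            function(i) all(dev[i:(i + run - 1)]), NA))
  sustained <- sustained[sustained > n_early]
  onset0 <- if (length(sustained) > 0) tt[sustained[1] - 1L]
            else tt[n] - (tt[n] - tt[1]) / 4
  fit <- fit_reversion_approach(tt, xx, t0_init = onset0)
  if (is.null(fit)) return(flag(event, "fit_failed"))
  # a time constant longer than the post-onset window is not
  # identifiable (the saturating branch has degenerated to a line), and
  # the branch needs a handful of samples to pin the curvature at all
  n_sat <- sum(tt > fit$t0)
  if (fit$t_r > tt[n] - fit$t0 || n_sat < 10)
    return(flag(event, "t_r_unidentifiable"))
  event$fitted <- TRUE
  event$A <- fit$A
  event$t_r_ms <- fit$t_r * 1000
  event$offset <- fit$offset
  event$onset_index <- i0 + max(which(tt <= fit$t0)) - 1L
  event$resid_sd <- fit$resid_sd
  event$flag <- "ok"
  event
}

#' Fit the linear-to-saturating approach model of a reversion
#'
#' Composite model of the approach to a reversal point: constant-velocity
#' motion for `t <= t0` rolling off into
#' `x(t) = A (1 - exp(-(t - t0)/t_r)) + c` for `t > t0`, continuous in
#' value and slope at `t0` (the linear slope is `A / t_r`). All four
#' parameters (`A`, `t_r`, `c`, `t0`) are fitted by least squares.
#'
#' @param t,x approach window samples (s, nm), ending at the reversal.
#' @param t0_init initial guess for the onset (defaults to 3/4 of the
#'   window).
#' @return list with `A`, `t_r`, `offset`, `t0`, `resid_sd`, or `NULL`
#'   when the fit fails.
#' @export
fit_reversion_approach <- function(t, x, t0_init = NULL) {
  n <- length(t)
  t0_init <- t0_init %||% (t[1] + 0.75 * (t[n] - t[1]))
  t0_init <- min(max(t0_init, t[1]), t[n] - 0.05 * (t[n] - t[1]))
  A0 <- x[n] - x[which.min(abs(t - t0_init))]
  if (A0 == 0) A0 <- x[n] - x[1]
  if (A0 == 0) return(NULL)
  model <- function(p) {
    A <- p[1]; tr <- p[2]; c0 <- p[3]; t0 <- p[4]
    ifelse(t <= t0, c0 + (A / tr) * (t - t0),
           c0 + A * (1 - exp(-(t - t0) / tr)))
  }
  st <- c(A0, max((t[n] - t0_init) / 3, 0.02), x[which.min(abs(t - t0_init))],
          t0_init)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = st, fn = function(p) x - model(p),
                       lower = c(-Inf, 1e-3, -Inf, t[1]),
                       upper = c(Inf, Inf, Inf, t[n]),
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) return(NULL)
  p <- fit$par
  list(A = p[1], t_r = p[2], offset = p[3], t0 = p[4],
       resid_sd = sqrt(fit$deviance / max(n - 4, 1)))
}

#' Fit a saturating exponential to a slowing-down window
#'
#' Least-squares fit of `x(t) = A (1 - exp(-(t - t[1]) / t_r)) + c` to a
#' position window, the functional form of the slowing-down phase that
#' precedes a wave-shaped reversion.
#'
#' @param t,x time (s) and position (nm) samples of the window.
#' @return list with `A` (nm), `t_r` (s), `offset` (nm), `resid_sd`, or
#'   `NULL` when the fit does not converge.
#' @export
fit_saturating_exponential <- function(t, x) {
  tf <- t - t[1]
  A0 <- x[length(x)] - x[1]
  st <- list(A = A0, tr = max(tf[length(tf)] / 3, 0.02), c = x[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(x ~ A * (1 - exp(-tf / tr)) + c, start = st,
                      lower = c(A = -Inf, tr = 1e-4, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(A = unname(cf["A"]), t_r = unname(cf["tr"]), offset = unname(cf["c"]),
       resid_sd = stats::sd(stats::resid(fit)))
}

#' Characteristic rise time of a set of reversions
#'
#' The distribution of fitted rise times follows an exponential decay;
#' its characteristic scale is recovered by fitting the decay of the
#' rise-time histogram (Poisson log-linear regression of bin counts on
#' bin centers, from the modal bin onward), with a bootstrap standard
#' error. This estimator reads off the decay constant of the bulk and is
#' insensitive to the few large outliers that survive fit-quality
#' filtering.
#'
#' @param events list of fitted `reversion_event`s, or a numeric vector of
#'   rise times (ms). Unfitted events are excluded.
#' @param bin_width_ms histogram bin width for the decay fit (ms).
#' @param min_events fewest fitted events required for an estimate.
#' @param n_boot bootstrap replicates for the uncertainty.
#' @return list with `t_r_ms` (characteristic decay scale), `se_ms`, `n`;
#'   or a flagged result with `t_r_ms = NA` when too few events are
#'   available or the distribution does not decay.
#' @export
rise_time_statistics <- function(events, bin_width_ms = 100,
                                 min_events = 20, n_boot = 200) {
  tr <- if (is.numeric(events)) events
        else vapply(Filter(function(e) isTRUE(e$fitted), events),
                    function(e) e$t_r_ms, 0)
  tr <- tr[is.finite(tr) & tr > 0]
  n <- length(tr)
  if (n < min_events)
    return(list(t_r_ms = NA_real_, se_ms = NA_real_, n = n,
                flag = "too_few_events"))
  est <- function(x) {
    breaks <- seq(0, max(x) + bin_width_ms, by = bin_width_ms)
    cnt <- tabulate(findInterval(x, breaks), nbins = length(breaks) - 1)
    mids <- breaks[-1] - bin_width_ms / 2
    from <- which.max(cnt)  # decay region starts at the mode
    cnt <- cnt[from:length(cnt)]; mids <- mids[from:length(mids)]
    fit <- suppressWarnings(
      stats::glm(cnt ~ mids, family = stats::poisson()))
    b <- stats::coef(fit)[["mids"]]
    if (!is.finite(b) || b >= 0) return(NA_real_)
    -1 / b
  }
  scale <- est(tr)
  if (!is.finite(scale))
    return(list(t_r_ms = NA_real_, se_ms = NA_real_, n = n,
                flag = "no_decay"))
  boot <- vapply(seq_len(n_boot),
                 function(i) est(sample(tr, n, replace = TRUE)), 0)
  list(t_r_ms = scale, se_ms = stats::sd(boot, na.rm = TRUE), n = n,
       flag = "ok")
}

#' Fit all reversions of an ensemble
#'
#' Convenience wrapper: detects and fits reversions trajectory by
#' trajectory and returns one row per event.
#'
#' @param trajectories list of `cargo_trajectory` objects.
#' @param ... passed to [detect_reversions()] and [fit_rise_time()].
#' @return data frame with one row per detected event (`t_rev`,
#'   `direction`, `back_displacement`, `t_r_ms`, `A`, `fitted`, `flag`).
#' @export
reversion_table <- function(trajectories, ...) {
  dots <- list(...)
  det_args <- dots[names(dots) %in% c("min_back", "min_dur", "smooth_window")]
  fit_args <- dots[names(dots) %in% c("band_sigma", "early_frac",
                                      "min_fit_samples")]
  rows <- list()
  for (ti in seq_along(trajectories)) {
    traj <- trajectories[[ti]]
    evs <- do.call(detect_reversions, c(list(traj), det_args))
    for (ev in evs) {
      ev <- do.call(fit_rise_time, c(list(ev, traj), fit_args))
      rows[[length(rows) + 1]] <- data.frame(
        traj = ti, t_rev = ev$t_rev, direction = ev$direction,
        back_displacement = ev$back_displacement,
        back_duration = ev$back_duration,
        t_r_ms = if (isTRUE(ev$fitted)) ev$t_r_ms else NA_real_,
        A = if (isTRUE(ev$fitted)) ev$A else NA_real_,
        fitted = isTRUE(ev$fitted), flag = ev$flag %||% "ok")
    }
  }
  if (length(rows) == 0)
    return(data.frame(traj = integer(0), t_rev = numeric(0),
                      direction = numeric(0), back_displacement = numeric(0),
                      back_duration = numeric(0), t_r_ms = numeric(0),
                      A = numeric(0), fitted = logical(0),
                      flag = character(0)))
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
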