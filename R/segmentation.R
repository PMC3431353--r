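# Segmental-velocity analysis: processive-period selection, 40-point
# constant-velocity segments, state-resolved velocity histograms, spatial
# motor distributions and the pulling-motor ratio mu.

# centered moving average with shrinking windows at the edges
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  h <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Zigzag split of a path into alternating-direction legs: a leg ends when
# the path retraces more than `threshold` from its running extremum. Returns
# turning-point indices (first and last index included), trimmed to extrema.
zigzag_points <- function(x, threshold) {
  n <- length(x)
  if (n < 2) return(c(1L, n))
  turns <- integer(0)
  dir <- 0L
  ext_i <- 1L; min_i <- 1L; max_i <- 1L
  for (i in 2:n) {
    if (dir == 0L) {
      if (x[i] < x[min_i]) min_i <- i
      if (x[i] > x[max_i]) max_i <- i
      if (x[i] - x[min_i] > threshold) {
        dir <- 1L; turns <- c(turns, min_i); ext_i <- i
      } else if (x[max_i] - x[i] > threshold) {
        dir <- -1L; turns <- c(turns, max_i); ext_i <- i
      }
    } else if (dir == 1L) {
      if (x[i] > x[ext_i]) ext_i <- i
      if (x[ext_i] - x[i] > threshold) {
        turns <- c(turns, ext_i); dir <- -1L; ext_i <- i
      }
    } else {
      if (x[i] < x[ext_i]) ext_i <- i
      if (x[i] - x[ext_i] > threshold) {
        turns <- c(turns, ext_i); dir <- 1L; ext_i <- i
      }
    }
  }
  if (dir == 0L) return(c(1L, n))
  c(turns, ext_i)
}

# extract (t, x) from a cargo_trajectory or a 2-column data frame
traj_tx <- function(traj) {
  if (inherits(traj, "cargo_trajectory")) {
    list(t = traj$t, x = traj$x_c)
  } else if (is.data.frame(traj) && ncol(traj) >= 2) {
    list(t = traj[[1]], x = traj[[2]])
  } else stop("expected a cargo_trajectory or a (t, x) data frame")
}

#' Select processive periods of a trajectory
#'
#' Splits the trajectory into maximal single-direction runs: on a smoothed
#' copy of the path, a run ends when the cargo retraces more than
#' `max_backtrack` from its running extremum; runs are trimmed to their
#' extrema and kept when their net displacement reaches `min_run`.
#'
#' @param traj a `cargo_trajectory` or data frame with columns (t, x).
#' @param min_run minimum net displacement of a period (nm).
#' @param max_backtrack tolerated retracement within a period (nm).
#' @param smooth_window smoothing window for direction detection (s).
#' @return a data frame with columns `start`, `end` (sample indices into
#'   the raw trajectory), `direction` (+1/-1) and `displacement` (nm);
#'   intervals do not overlap.
#' @export
select_processive_periods <- function(traj, min_run = 100,
                                      max_backtrack = 60,
                                      smooth_window = 0.1) {
  tx <- traj_tx(traj)
  n <- length(tx$x)
  empty <- data.frame(start = integer(0), end = integer(0),
                      direction = integer(0), displacement = numeric(0))
  if (n < 40) return(empty)
  dt_s <- stats::median(diff(tx$t))
  w <- max(1L, round(smooth_window / dt_s))
  xs <- moving_average(tx$x, w)
  tp <- zigzag_points(xs, max_backtrack)
  if (length(tp) < 2) return(empty)
  out <- data.frame(start = tp[-length(tp)], end = tp[-1])
  out$start[-1] <- out$start[-1] + 1L  # keep intervals disjoint
  disp <- tx$x[out$end] - tx$x[out$start]
  out$direction <- ifelse(disp >= 0, 1L, -1L)
  out$displacement <- disp
  out[abs(disp) >= min_run, , drop = FALSE]
}

#' Extract constant-velocity segments
#'
#' Cuts each processive period into consecutive non-overlapping windows of
#' `seg_len` samples, fits position on time by ordinary least squares and
#' keeps windows with speed above `min_speed` and |Pearson r| above
#' `min_corr`. Residual points shorter than a full window are discarded.
#' For simulator trajectories the per-sample attachment `(nf, nb)` and
#' pulling `(qf, qb)` states of each segment are recorded as fractional
#' occupancies.
#'
#' @param traj a `cargo_trajectory` or (t, x) data frame.
#' @param intervals result of [select_processive_periods()]; computed with
#'   defaults when omitted.
#' @param seg_len samples per segment (40 points at 0.01 s = 0.4 s).
#' @param min_speed speed filter (nm/s).
#' @param min_corr linearity filter on |Pearson r|.
#' @return an object of class `segment_set`: `$segments` (one row per
#'   accepted segment: `start`, `v`, `r`, `direction`) and `$states`
#'   (per-segment state occupancy fractions; `NULL` for plain (t,x) input).
#' @export
extract_segments <- function(traj, intervals = NULL, seg_len = 40,
                             min_speed = 100, min_corr = 0.98) {
  if (is.null(intervals)) intervals <- select_processive_periods(traj)
  tx <- traj_tx(traj)
  has_states <- inherits(traj, "cargo_trajectory") && !is.null(traj$qf)
  seg_rows <- list(); state_rows <- list(); m <- 0L
  for (iv in seq_len(nrow(intervals))) {
    i0 <- intervals$start[iv]; i1 <- intervals$end[iv]
    n_win <- (i1 - i0 + 1L) %/% seg_len
    if (n_win < 1) next
    for (wi in seq_len(n_win)) {
      a <- i0 + (wi - 1L) * seg_len
      b <- a + seg_len - 1L
      tt <- tx$t[a:b]; xx <- tx$x[a:b]
      vt <- stats::var(tt)
      v <- stats::cov(tt, xx) / vt
      r <- suppressWarnings(stats::cor(tt, xx))
      if (!is.finite(r) || abs(v) <= min_speed || abs(r) <= min_corr) next
      m <- m + 1L
      seg_rows[[m]] <- data.frame(start = a, v = v, r = r,
                                  direction = ifelse(v >= 0, 1L, -1L))
      if (has_states) {
        tab <- table(qf = traj$qf[a:b], qb = traj$qb[a:b],
                     nf = traj$nf[a:b], nb = traj$nb[a:b])
        df <- as.data.frame(tab, stringsAsFactors = FALSE)
        df <- df[df$Freq > 0, , drop = FALSE]
        state_rows[[m]] <- data.frame(
          seg = m,
          qf = as.integer(df$qf), qb = as.integer(df$qb),
          nf = as.integer(df$nf), nb = as.integer(df$nb),
          frac = df$Freq / seg_len)
      }
    }
  }
  segments <- if (m > 0) do.call(rbind, seg_rows) else
    data.frame(start = integer(0), v = numeric(0), r = numeric(0),
               direction = integer(0))
  states <- if (has_states && m > 0) do.call(rbind, state_rows) else NULL
  structure(list(segments = segments, states = states,
                 seg_len = seg_len, sample_dt =
                   if (length(tx$t) > 1) stats::median(diff(tx$t)) else NA),
            class = "segment_set")
}

# merge segment_sets from several trajectories (re-indexing $states$seg)
combine_segment_sets <- function(sets) {
  sets <- Filter(function(s) nrow(s$segments) > 0, sets)
  if (length(sets) == 0)
    return(structure(list(segments = data.frame(start = integer(0),
                                                v = numeric(0), r = numeric(0),
                                                direction = integer(0)),
                          states = NULL, seg_len = 40, sample_dt = NA),
                     class = "segment_set"))
  offs <- cumsum(c(0, vapply(sets, function(s) nrow(s$segments), 0)))
  segments <- do.call(rbind, lapply(sets, `[[`, "segments"))
  states <- NULL
  st <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]$states
    if (!is.null(s)) s$seg <- s$seg + offs[i]
    s
  })
  st <- Filter(Negate(is.null), st)
  if (length(st) == length(sets)) states <- do.call(rbind, st)
  structure(list(segments = segments, states = states,
                 seg_len = sets[[1]]$seg_len, sample_dt = sets[[1]]$sample_dt),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set: %d accepted segments", nrow(x$segments)))
  if (nrow(x$segments) > 0)
    cat(sprintf(" (%.0f%% backward)", 100 * mean(x$segments$v < 0)))
  cat("\n")
  invisible(x)
}

#' Segmental-velocity histogram, optionally state-resolved
#'
#' Each accepted segment contributes weight 1 to the bin holding its fitted
#' velocity. When state occupancies are available, every pulling state
#' `(qf, qb)` and attachment state `(nf, nb)` receives that segment's
#' fractional occupancy as weight, so the state-resolved curves sum
#' bin-wise to the total. Normalization `max1` rescales all weights so the
#' global maximum equals 1 (the convention used for comparing velocity
#' distributions); `count` leaves raw weights.
#'
#' @param segset a `segment_set`.
#' @param bin_width histogram bin width (nm/s).
#' @param mode `"max1"` or `"count"`.
#' @param direction `"both"`, `"forward"` or `"backward"`; for a single
#'   branch the histogram is built on the speed axis `|v|`.
#' @return an object of class `velocity_histogram` with `breaks`, `mids`,
#'   `weights`, and (if available) matrices `pulling` and `attachment`
#'   (bins x states, column names like `"(2,1)"`).
#' @export
velocity_histogram <- function(segset, bin_width = 55,
                               mode = c("max1", "count"),
                               direction = c("both", "forward", "backward")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  seg <- segset$segments
  keep <- switch(direction,
                 both = rep(TRUE, nrow(seg)),
                 forward = seg$v > 0,
                 backward = seg$v < 0)
  idx <- which(keep)
  if (length(idx) == 0) {
    h <- structure(list(breaks = numeric(0), mids = numeric(0),
                        weights = numeric(0), pulling = NULL,
                        attachment = NULL, mode = mode, empty = TRUE,
                        bin_width = bin_width, direction = direction),
                   class = "velocity_histogram")
    warning("no segments for direction '", direction, "'; empty histogram")
    return(h)
  }
  v <- seg$v[idx]
  if (direction != "both") v <- abs(v)
  breaks <- seq(floor(min(v) / bin_width) * bin_width,
                ceiling(max(v) / bin_width) * bin_width, by = bin_width)
  if (length(breaks) < 2) breaks <- c(breaks, breaks + bin_width)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  weights <- as.numeric(tabulate(bin, nbins = nb))
  pulling <- attachment <- NULL
  if (!is.null(segset$states)) {
    st <- segset$states[segset$states$seg %in% idx, , drop = FALSE]
    st$bin <- bin[match(st$seg, idx)]
    pl <- paste0("(", st$qf, ",", st$qb, ")")
    al <- paste0("(", st$nf, ",", st$nb, ")")
    pulling <- as.matrix(stats::xtabs(frac ~ bin + lab,
      data.frame(bin = factor(st$bin, levels = seq_len(nb)), lab = pl,
                 frac = st$frac)))
    attachment <- as.matrix(stats::xtabs(frac ~ bin + lab,
      data.frame(bin = factor(st$bin, levels = seq_len(nb)), lab = al,
                 frac = st$frac)))
  }
  norm <- if (mode == "max1") max(weights) else 1
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 weights = weights / norm,
                 pulling = if (!is.null(pulling)) pulling / norm else NULL,
                 attachment = if (!is.null(attachment)) attachment / norm else NULL,
                 mode = mode, empty = FALSE, bin_width = bin_width,
                 direction = direction, n_segments = length(idx)),
            class = "velocity_histogram")
}

#' @export
print.velocity_histogram <- function(x, ...) {
  if (isTRUE(x$empty)) { cat("velocity_histogram: empty\n"); return(invisible(x)) }
  cat(sprintf("velocity_histogram: %d segments, %d bins of %g nm/s (%s, %s)\n",
              x$n_segments, length(x$mids), x$bin_width, x$direction, x$mode))
  invisible(x)
}

#' Dominant pulling state within a velocity window
#'
#' Sums the state-resolved weights over the bins whose centers fall in
#' `[vmin, vmax]` and returns the state with the largest total.
#'
#' @param hist a state-resolved `velocity_histogram`.
#' @param vmin,vmax velocity window (nm/s, on the histogram axis).
#' @param which `"pulling"` or `"attachment"`.
#' @return named numeric vector of state weights, decreasing.
#' @export
dominant_state <- function(hist, vmin, vmax, which = c("pulling", "attachment")) {
  which <- match.arg(which)
  m <- hist[[which]]
  if (is.null(m)) stop("histogram carries no state decomposition")
  sel <- hist$mids >= vmin & hist$mids <= vmax
  sort(colSums(m[sel, , drop = FALSE]), decreasing = TRUE)
}

#' Fraction of backward-directed segments
#'
#' @param segset a `segment_set` (must contain at least one segment).
#' @return `count(v < 0) / count(all)` over accepted segments.
#' @export
backward_fraction <- function(segset) {
  v <- segset$segments$v
  if (length(v) == 0) stop("no accepted segments")
  mean(v < 0)
}

#' Spatial distribution of motors around the cargo and the ratio mu
#'
#' Pools motor positions relative to the cargo over every sample of every
#' accepted forward-moving segment whose velocity lies in the window, and
#' computes `mu`, the ratio of pulling forward motors (`x - x_c > x0`) to
#' pulling backward motors (`x - x_c < -x0`). Both per-team histograms are
#' normalized by the same constant (total pooled samples) so the area
#' quotient beyond `+/- x0` equals the count ratio.
#'
#' @param trajectories a `cargo_trajectory` or list of them.
#' @param velocity_window `c(vmin, vmax)` in nm/s (positive; forward
#'   segments only, following the convention used for spatial analyses).
#' @param segsets optional list of precomputed `segment_set`s matching
#'   `trajectories` (saves re-segmentation).
#' @param bin_width histogram bin width for the spatial distributions (nm).
#' @param ... passed to [extract_segments()] when segsets are computed here.
#' @return list with `mu`, pulling/attached counts per team, and per-team
#'   relative-position histograms (`d_breaks`, `forward`, `backward`).
#'   `mu` is `Inf` (flagged) when no backward motor is pulling and `NA`
#'   when no segment falls in the window.
#' @export
motor_spatial_distribution <- function(trajectories, velocity_window,
                                       segsets = NULL, bin_width = 10, ...) {
  if (inherits(trajectories, "cargo_trajectory"))
    trajectories <- list(trajectories)
  if (is.null(segsets))
    segsets <- lapply(trajectories, extract_segments, ...)
  acc <- spatial_accumulator(velocity_window, bin_width)
  for (i in seq_along(trajectories))
    acc <- spatial_accumulate(acc, trajectories[[i]], segsets[[i]])
  spatial_finalize(acc)
}

# streaming accumulator so ensembles need not be held in memory at once
spatial_accumulator <- function(window, bin_width = 10, d_max = 1500) {
  list(window = window, bin_width = bin_width,
       breaks = seq(-d_max, d_max, by = bin_width),
       cnt_f = 0, cnt_b = 0, pull_f = 0, pull_b = 0, n_samples = 0,
       hist_f = 0, hist_b = 0)
}

spatial_accumulate <- function(acc, traj, segset) {
  seg <- segset$segments
  sel <- which(seg$v > 0 & seg$v >= acc$window[1] & seg$v <= acc$window[2])
  if (length(sel) == 0) return(acc)
  sp <- motor_species_list(traj$config)
  pol <- vapply(sp, `[[`, 0, "polarity")
  x0 <- vapply(sp, `[[`, 0, "x0")
  L <- segset$seg_len
  rows <- unlist(lapply(seg$start[sel], function(a) a:(a + L - 1L)))
  d <- traj$x_m[rows, , drop = FALSE] - traj$x_c[rows]
  for (j in seq_along(pol)) {
    dj <- d[, j]; dj <- dj[!is.na(dj)]
    hj <- tabulate(findInterval(pmin(pmax(dj, acc$breaks[1]),
                                     acc$breaks[length(acc$breaks)] - 1e-9),
                                acc$breaks),
                   nbins = length(acc$breaks) - 1)
    if (pol[j] > 0) {
      acc$cnt_f <- acc$cnt_f + length(dj)
      acc$pull_f <- acc$pull_f + sum(dj > x0[j])
      acc$hist_f <- acc$hist_f + hj
    } else {
      acc$cnt_b <- acc$cnt_b + length(dj)
      acc$pull_b <- acc$pull_b + sum(dj < -x0[j])
      acc$hist_b <- acc$hist_b + hj
    }
  }
  acc$n_samples <- acc$n_samples + length(rows)
  acc
}

spatial_finalize <- function(acc) {
  mu <- if (acc$n_samples == 0) NA_real_
        else if (acc$pull_b == 0) Inf
        else acc$pull_f / acc$pull_b
  norm <- max(acc$n_samples, 1) * acc$bin_width
  list(mu = mu,
       n_pulling_forward = acc$pull_f, n_pulling_backward = acc$pull_b,
       n_attached_forward = acc$cnt_f, n_attached_backward = acc$cnt_b,
       n_samples = acc$n_samples,
       d_breaks = acc$breaks,
       forward = acc$hist_f / norm, backward = acc$hist_b / norm,
       velocity_window = acc$window,
       no_backward_pulling = is.infinite(mu),
       no_segments = acc$n_samples == 0)
}
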