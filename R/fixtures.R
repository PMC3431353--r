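# Deterministic synthetic objects with known ground truth, used to test the
# analysis pipeline independently of the simulator.

#' Generate a synthetic fixture
#'
#' Produces toy trajectories or histograms with analytically known truth:
#' \describe{
#'   \item{`line`}{constant-velocity path; params `v` (nm/s), `duration`
#'     (s), `sample_dt` (s), `noise_sd` (nm, optional i.i.d. Gaussian).}
#'   \item{`triangle`}{alternating forward/backward ramps; params `v`,
#'     `half_period` (s), `duration`, `sample_dt`.}
#'   \item{`exp_reversion`}{linear approach that rolls off along
#'     `x(t) = A (1 - exp(-t/t_r)) + c` and then reverses; params `A`
#'     (nm), `t_r` (s), `offset` (nm), `v_back` (nm/s), `lin_duration`,
#'     `sat_duration`, `back_duration` (s), `sample_dt`, `noise_sd`.
#'     The approach velocity is `A / t_r` so the rise is smooth.}
#'   \item{`mixture_hist`}{exact 4-Gaussian mixture evaluated on a bin
#'     grid; params `centers`, `amps`, `sigmas` (nm/s), `bin_width`,
#'     `vmax`.}
#' }
#'
#' @param kind one of `"line"`, `"triangle"`, `"exp_reversion"`,
#'   `"mixture_hist"`.
#' @param params named list of parameters (see Details); unset entries
#'   take the defaults above.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return a (t, x) data frame with attribute `truth`, or for
#'   `mixture_hist` a `velocity_histogram`-compatible list with attribute
#'   `truth`.
#' @export
make_fixture <- function(kind = c("line", "triangle", "exp_reversion",
                                  "mixture_hist"),
                         params = list(), seed = 1) {
  kind <- match.arg(kind)
  p <- function(name, default) params[[name]] %||% default
  switch(kind,
    line = {
      v <- p("v", 400); dur <- p("duration", 20)
      dt <- p("sample_dt", 0.01); sd0 <- p("noise_sd", 0)
      t <- seq(0, dur, by = dt)
      x <- v * t
      if (sd0 > 0) { set.seed(seed); x <- x + stats::rnorm(length(t), 0, sd0) }
      structure(data.frame(t = t, x = x), truth = list(v = v))
    },
    triangle = {
      v <- p("v", 400); hp <- p("half_period", 2)
      dur <- p("duration", 8); dt <- p("sample_dt", 0.01)
      t <- seq(0, dur, by = dt)
      phase <- (t %% (2 * hp))
      x_cycle <- ifelse(phase <= hp, v * phase, v * hp - v * (phase - hp))
      n_cycles <- floor(t / (2 * hp))
      structure(data.frame(t = t, x = x_cycle + 0 * n_cycles),
                truth = list(v = v, half_period = hp))
    },
    exp_reversion = {
      A <- p("A", 604); tr <- p("t_r", 0.75); c0 <- p("offset", 53)
      v_back <- p("v_back", -300)
      # the roll-off ends just before the reversal, as in real
      # wave-shaped events: ~2.5 time constants of saturation
      lin <- p("lin_duration", 2)
      sat <- p("sat_duration", max(2.5 * tr, 0.3))
      back <- p("back_duration", 2)
      dt <- p("sample_dt", 0.01); sd0 <- p("noise_sd", 0)
      v_in <- A / tr  # matches d/dt of the saturating branch at t = 0
      t <- seq(0, lin + sat + back, by = dt)
      x <- numeric(length(t))
      x_lin_end <- c0
      seg1 <- t <= lin
      x[seg1] <- c0 - v_in * (lin - t[seg1])
      seg2 <- t > lin & t <= lin + sat
      x[seg2] <- A * (1 - exp(-(t[seg2] - lin) / tr)) + c0
      x_rev <- A * (1 - exp(-sat / tr)) + c0
      seg3 <- t > lin + sat
      x[seg3] <- x_rev + v_back * (t[seg3] - lin - sat)
      if (sd0 > 0) { set.seed(seed); x <- x + stats::rnorm(length(t), 0, sd0) }
      structure(data.frame(t = t, x = x),
                truth = list(A = A, t_r = tr, offset = c0,
                             t_rev = lin + sat))
    },
    mixture_hist = {
      centers <- p("centers", 250 * 1:4)
      amps <- p("amps", c(1, 0.8, 0.4, 0.15))
      sigmas <- p("sigmas", rep(80, 4))
      bw <- p("bin_width", 25); vmax <- p("vmax", 1400)
      mids <- seq(bw / 2, vmax, by = bw)
      y <- rowSums(vapply(seq_along(centers), function(m)
        amps[m] * exp(-(mids - centers[m])^2 / (2 * sigmas[m]^2)),
        numeric(length(mids))))
      structure(list(mids = mids, weights = y / max(y),
                     breaks = seq(0, vmax, by = bw), bin_width = bw,
                     mode = "max1", empty = FALSE),
                truth = list(centers = centers, amps = amps / max(y),
                             sigmas = sigmas))
    })
}
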