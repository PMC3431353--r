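# Stochastic simulation of the coupled cargo-motor dynamics.
#
# The production inner loop lives in src/simulate.cpp; the R functions here
# define the elementary rates (shared contract with the C++ code), a
# single-step reference implementation used for small-system diagnostics,
# and the user-facing simulate()/simulate_ensemble() drivers.

#' Elastic linker force on the cargo
#'
#' The linker is slack (zero force) while the motor sits within `x0` of the
#' cargo and Hookean beyond, always pulling the cargo toward the motor:
#' `f = k (d - x0)` for `d >= x0`, `f = k (d + x0)` for `d <= -x0`, else 0,
#' with `d = x_motor - x_cargo`.
#'
#' @param d motor-cargo separation(s) (nm), signed.
#' @param k linker stiffness (pN/nm).
#' @param x0 slack half-width (nm).
#' @return signed force on the cargo (pN); vectorized over `d`.
#' @export
linker_force <- function(d, k, x0) {
  sign(d) * k * pmax(abs(d) - x0, 0)
}

#' Load-dependent stepping rate
#'
#' The mean motor velocity under load is `v(L) = v0 (1 - (L/Fs)^w)` for
#' opposing loads `0 <= L <= Fs`, zero at and beyond stall, and capped at
#' `v0` for assisting loads (`L < 0`). A motor never steps backward. The
#' stepping rate is `v(L)/dx`.
#'
#' @param L load on the motor (pN), positive when opposing its polarity.
#' @param v0 zero-load velocity (nm/s).
#' @param Fs stall force (pN).
#' @param w nonlinearity exponent.
#' @param dx step length (nm).
#' @return stepping probability per unit time (1/s); vectorized over `L`.
#' @export
stepping_rate <- function(L, v0, Fs, w, dx) {
  stopifnot(dx > 0)
  v <- ifelse(L <= 0, v0,
              ifelse(L >= Fs, 0, v0 * (1 - (L / Fs)^w)))
  v / dx
}

#' Load-dependent detachment rate
#'
#' Kramers-type exponential load dependence: `eps * exp(|L| / Fd)`.
#'
#' @param L load (pN); only its magnitude matters.
#' @param eps zero-load detachment rate (1/s).
#' @param Fd detachment force (pN).
#' @return detachment probability per unit time (1/s); vectorized.
#' @export
detachment_rate <- function(L, eps, Fd) {
  stopifnot(Fd > 0)
  eps * exp(abs(L) / Fd)
}

#' Per-step event probabilities for one motor
#'
#' Analytic first-order probabilities of the three elementary events over
#' one integration step `dt`, given the motor-cargo separation. Used by the
#' engine (identically, in compiled code) and by enumeration oracles.
#'
#' @param d motor-cargo separation (nm); ignored for `p_attach`.
#' @param sp a [motor_species()].
#' @param dt time step (s).
#' @return list with `p_step`, `p_detach` (attached motor) and `p_attach`
#'   (detached motor).
#' @export
motor_event_probs <- function(d, sp, dt) {
  f <- linker_force(d, sp$k, sp$x0)
  L <- sp$polarity * f
  list(p_step = stepping_rate(L, sp$v0, sp$Fs, sp$w, sp$dx) * dt,
       p_detach = detachment_rate(f, sp$eps, sp$Fd) * dt,
       p_attach = sp$pi_att * dt)
}

#' Lattice sites available for attachment
#'
#' All sites `j dx` strictly inside the slack zone `|x - x_c| < x0`; a
#' motor attaching there exerts zero force immediately (relaxed linker).
#'
#' @param x_c cargo position (nm).
#' @param x0 slack half-width (nm).
#' @param dx lattice spacing (nm).
#' @return numeric vector of site positions (nm).
#' @export
attach_sites <- function(x_c, x0, dx) {
  jlo <- ceiling((x_c - x0) / dx)
  jhi <- floor((x_c + x0) / dx)
  if (jlo * dx <= x_c - x0) jlo <- jlo + 1
  if (jhi * dx >= x_c + x0) jhi <- jhi - 1
  if (jhi < jlo) stop("no lattice site in attachment zone")
  seq(jlo, jhi) * dx
}

#' Construct a system state
#'
#' @param x_c cargo position (nm).
#' @param attached logical vector, one per motor (forward team first).
#' @param x_m motor lattice positions (nm; `NA` where detached).
#' @param t time (s).
#' @return an object of class `system_state`.
#' @export
system_state <- function(x_c, attached, x_m, t = 0) {
  stopifnot(length(attached) == length(x_m))
  structure(list(x_c = x_c, attached = attached, x_m = x_m, t = t),
            class = "system_state")
}

#' Advance the system by one time step (reference implementation)
#'
#' Plain-R Euler-Maruyama step identical in law to one iteration of the
#' compiled engine: cargo drift + thermal noise, then independent Bernoulli
#' step/detach/attach events per motor. Uses R's RNG. Intended for
#' small-system diagnostics and oracle tests, not production runs.
#'
#' @param state a [system_state()]; motors ordered forward team then
#'   backward team, sized per the config.
#' @param cfg a `model_config`.
#' @param dt time step (defaults to `cfg$dt`).
#' @return the updated `system_state`.
#' @export
advance_state <- function(state, cfg, dt = cfg$dt) {
  species <- motor_species_list(cfg)
  M <- length(species)
  stopifnot(length(state$attached) == M)
  f <- numeric(M)
  for (i in seq_len(M)) {
    if (state$attached[i])
      f[i] <- linker_force(state$x_m[i] - state$x_c,
                           species[[i]]$k, species[[i]]$x0)
  }
  g <- cfg$env$gamma
  x_c <- state$x_c + sum(f) / g * dt +
    if (cfg$noise) sqrt(2 * cfg$env$kBT * dt / g) * stats::rnorm(1) else 0
  for (i in seq_len(M)) {
    sp <- species[[i]]
    if (state$attached[i]) {
      L <- sp$polarity * f[i]
      p_step <- stepping_rate(L, sp$v0, sp$Fs, sp$w, sp$dx) * dt
      p_det <- detachment_rate(f[i], sp$eps, sp$Fd) * dt
      if (p_step > 0.1 || p_det > 0.1)
        stop("dt_too_large: per-event probability exceeded 0.1")
      if (stats::runif(1) < p_step) state$x_m[i] <- state$x_m[i] + sp$polarity * sp$dx
      if (stats::runif(1) < p_det) {
        state$attached[i] <- FALSE
        state$x_m[i] <- NA_real_
      }
    } else {
      p_att <- sp$pi_att * dt
      if (p_att > 0.1) stop("dt_too_large: per-event probability exceeded 0.1")
      if (stats::runif(1) < p_att) {
        state$attached[i] <- TRUE
        state$x_m[i] <- sample(attach_sites(state$x_c, sp$x0, sp$dx), 1)
      }
    }
  }
  state$x_c <- x_c
  state$t <- state$t + dt
  state
}

# one motor_species entry per individual motor, forward team first
motor_species_list <- function(cfg) {
  c(rep(list(cfg$forward), cfg$forward$count),
    rep(list(cfg$backward), cfg$backward$count))
}

#' Simulate one cargo trajectory
#'
#' Runs the stochastic tug-of-war dynamics from an all-motors-engaged
#' initial condition (each motor at an independently drawn relaxed lattice
#' site, cargo at 0) until `t_max` or full detachment, sampling every
#' `sample_dt`. If the first-order guard trips (an event probability over
#' one `dt` exceeds 0.1) the run is repeated with `dt/10`.
#'
#' @param cfg a `model_config`.
#' @param seed RNG seed (defaults to `cfg$seed`); required.
#' @param stream sub-stream index used by [simulate_ensemble()]; each
#'   (seed, stream) pair gives an independent reproducible trajectory.
#' @return an object of class `cargo_trajectory`: uniformly sampled times,
#'   cargo positions, per-motor attachment flags and positions, attachment
#'   counts `(nf, nb)` and pulling counts `(qf, qb)`, plus config, seed and
#'   termination reason.
#' @export
simulate <- function(cfg, seed = cfg$seed, stream = 0) {
  validate_config(cfg)
  if (is.null(seed)) stop("simulate() needs a seed (cfg$seed or argument)")
  species <- motor_species_list(cfg)
  dt <- cfg$dt
  for (attempt in 1:3) {
    res <- tryCatch(
      .simulate_cpp(species, cfg$env$gamma, cfg$env$kBT, dt, cfg$t_max,
                    cfg$sample_dt, as.numeric(seed), as.integer(stream),
                    isTRUE(cfg$noise), isTRUE(cfg$stop_on_full_detach)),
      error = function(e) e)
    if (!inherits(res, "error")) break
    if (!grepl("dt_too_large", conditionMessage(res)) || attempt == 3)
      stop(res)
    dt <- dt / 10
  }
  traj <- list(t = res$t, x_c = res$x_c,
               attached = res$attached == 1L, x_m = res$x_m,
               nf = res$nf, nb = res$nb, qf = res$qf, qb = res$qb,
               config = cfg, seed = seed, stream = stream, dt_used = dt,
               termination = res$termination)
  class(traj) <- "cargo_trajectory"
  traj
}

#' Simulate an ensemble of independent trajectories
#'
#' Each trajectory runs on its own RNG stream derived deterministically
#' from `base_seed` and the trajectory index, so results are reproducible
#' and independent of execution order, and a longer ensemble extends a
#' shorter one with the same `base_seed`.
#'
#' @param cfg a `model_config`.
#' @param n_traj number of trajectories.
#' @param base_seed integer seed for the whole ensemble.
#' @return list of `cargo_trajectory` objects.
#' @export
simulate_ensemble <- function(cfg, n_traj, base_seed) {
  stopifnot(n_traj >= 1)
  lapply(seq_len(n_traj) - 1L,
         function(i) simulate(cfg, seed = base_seed, stream = i))
}

#' @export
print.cargo_trajectory <- function(x, ...) {
  cat(sprintf("cargo_trajectory: %d samples over %.2f s (%s)\n",
              length(x$t), max(x$t), x$termination))
  cat(sprintf("  displacement %.0f nm; motors %d forward + %d backward\n",
              x$x_c[length(x$x_c)] - x$x_c[1],
              x$config$forward$count, x$config$backward$count))
  invisible(x)
}

#' Coerce a trajectory to a data frame
#'
#' One row per sample: `t`, `x_c`, per-motor attachment flags `m<i>_att`
#' and positions `m<i>_x`, and the state counts `nf, nb, qf, qb`.
#' @param x a `cargo_trajectory`.
#' @param ... unused.
#' @export
as.data.frame.cargo_trajectory <- function(x, ...) {
  M <- ncol(x$x_m)
  df <- data.frame(t = x$t, x_c = x$x_c)
  for (i in seq_len(M)) {
    df[[sprintf("m%d_att", i)]] <- x$attached[, i]
    df[[sprintf("m%d_x", i)]] <- x$x_m[, i]
  }
  df$nf <- x$nf; df$nb <- x$nb; df$qf <- x$qf; df$qb <- x$qb
  df
}
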