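# Domain types and canonical parameter sets for the tug-of-war transport model.

# Physical constants used at the single point where derived quantities are
# computed. Boltzmann constant in pN nm / K; water viscosity in Pa s.
.kB_pN_nm <- 1.380649e-2
.eta_water_Pa_s <- 1.0e-3
# 1 Pa s = 1e-6 pN s / nm^2 (N s m^-2 -> pN s nm^-2)
.Pa_s_to_pN_s_nm2 <- 1.0e-6

#' Single-motor parameter set for one polarity
#'
#' Describes one motor species (kinesin-like forward or dynein-like backward
#' stepper) permanently linked to the cargo through an elastic linker that is
#' slack within `x0` of the cargo.
#'
#' @param polarity `+1` for forward (plus-end directed), `-1` for backward.
#' @param count number of motors of this species linked to the cargo.
#' @param v0 zero-load stepping velocity (nm/s).
#' @param Fs stall force (pN): the load at which stepping velocity reaches 0.
#' @param w exponent of the load-velocity nonlinearity (dimensionless).
#' @param eps zero-load detachment rate (1/s).
#' @param Fd detachment force (pN), the load scale of the exponential
#'   increase of the unbinding rate.
#' @param pi_att attachment rate of a detached motor (1/s).
#' @param k linker stiffness (pN/nm).
#' @param x0 slack half-width of the linker (nm); motors within `x0` of the
#'   cargo exert no force.
#' @param dx step length on the microtubule lattice (nm).
#' @return an object of class `motor_species`.
#' @export
motor_species <- function(polarity, count, v0 = 500, Fs = 6, w = 2,
                          eps = 0.2, Fd = 3, pi_att = 2, k = 0.02,
                          x0 = 110, dx = 8) {
  stopifnot(polarity %in% c(-1L, 1L))
  sp <- list(polarity = as.integer(polarity), count = as.integer(count),
             v0 = v0, Fs = Fs, w = w, eps = eps, Fd = Fd,
             pi_att = pi_att, k = k, x0 = x0, dx = dx)
  class(sp) <- "motor_species"
  validate_motor_species(sp)
  sp
}

validate_motor_species <- function(sp) {
  chk <- function(cond, msg) if (!cond) stop("invalid motor_species: ", msg,
                                             call. = FALSE)
  chk(sp$count >= 0, "count must be >= 0")
  chk(sp$v0 > 0, "v0 must be > 0")
  chk(sp$Fs > 0, "Fs must be > 0")
  chk(sp$w > 0, "w must be > 0")
  chk(sp$eps >= 0, "eps must be >= 0")
  chk(sp$Fd > 0, "Fd must be > 0")
  chk(sp$pi_att >= 0, "pi_att must be >= 0")
  chk(sp$k > 0, "k must be > 0")
  chk(sp$x0 > 0, "x0 must be > 0")
  chk(sp$dx > 0, "dx must be > 0")
  invisible(sp)
}

#' Cargo environment (viscosity, size, temperature)
#'
#' The drag is derived from the Stokes relation `gamma = 6 pi eta r` with
#' `eta = n_gamma * eta_water` (water viscosity 1e-3 Pa s); `kBT` is the
#' thermal energy in pN nm.
#'
#' @param n_gamma dimensionless viscosity relative to water.
#' @param r cargo radius (nm).
#' @param T temperature (K).
#' @return an object of class `transport_env` with derived `gamma`
#'   (pN s/nm) and `kBT` (pN nm).
#' @export
transport_env <- function(n_gamma = 500, r = 500, T = 300) {
  stopifnot(n_gamma > 0, r > 0, T > 0)
  eta <- n_gamma * .eta_water_Pa_s * .Pa_s_to_pN_s_nm2  # pN s / nm^2
  env <- list(n_gamma = n_gamma, r = r, T = T,
              gamma = 6 * pi * eta * r,
              kBT = .kB_pN_nm * T)
  class(env) <- "transport_env"
  env
}

#' Full model configuration
#'
#' @param forward,backward [motor_species()] objects for the two teams
#'   (polarities must be `+1` and `-1` respectively).
#' @param env a [transport_env()].
#' @param dt integration time step (s); must lie in 1e-7..1e-5.
#' @param t_max maximum simulated time (s).
#' @param sample_dt output sampling interval (s); must be >= 100 dt.
#' @param seed RNG seed for [simulate()] (integer or NULL).
#' @param stop_on_full_detach stop the run when no motor is attached.
#' @param noise include thermal noise on the cargo (fluctuation-dissipation
#'   amplitude `sqrt(2 kBT dt / gamma)`); only disabled for deterministic
#'   diagnostics.
#' @return an object of class `model_config`.
#' @export
model_config <- function(forward, backward, env = transport_env(),
                         dt = 1e-5, t_max = 20, sample_dt = 0.01,
                         seed = NULL, stop_on_full_detach = TRUE,
                         noise = TRUE) {
  cfg <- list(forward = forward, backward = backward, env = env,
              dt = dt, t_max = t_max, sample_dt = sample_dt,
              seed = seed, stop_on_full_detach = stop_on_full_detach,
              noise = noise)
  class(cfg) <- "model_config"
  validate_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks field types, motor invariants, the `dt` window and the sampling
#' constraint; returns the config invisibly or stops naming the offending
#' field.
#' @param cfg a `model_config`.
#' @export
validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("invalid model_config: ", msg,
                                             call. = FALSE)
  chk(inherits(cfg$forward, "motor_species"), "forward is not a motor_species")
  chk(inherits(cfg$backward, "motor_species"), "backward is not a motor_species")
  chk(inherits(cfg$env, "transport_env"), "env is not a transport_env")
  chk(cfg$forward$polarity == 1L, "forward team must have polarity +1")
  chk(cfg$backward$polarity == -1L, "backward team must have polarity -1")
  validate_motor_species(cfg$forward)
  validate_motor_species(cfg$backward)
  chk(cfg$dt >= 1e-7 - 1e-12 && cfg$dt <= 1e-5 + 1e-12,
      "dt must lie within 1e-7..1e-5 s")
  chk(cfg$sample_dt >= 100 * cfg$dt, "sample_dt must be >= 100 * dt")
  chk(cfg$t_max > 0, "t_max must be > 0")
  invisible(cfg)
}

#' Referential parameter set (RS)
#'
#' The canonical symmetric parameterization for melanosome transport:
#' two forward and two backward motors with identical single-motor
#' parameters (v0 = 500 nm/s, Fs = 6 pN, w = 2, eps = 0.2/s, Fd = 3 pN,
#' pi = 2/s, k = 0.02 pN/nm, x0 = 110 nm), cargo radius 500 nm in a medium
#' 500 times more viscous than water, at 300 K.
#'
#' @param ... overrides passed to both [motor_species()] constructors
#'   (e.g. `k = 0.3` for the stiff-linker variant).
#' @param N_f,N_b team sizes (defaults 2 and 2).
#' @param n_gamma relative viscosity (default 500).
#' @param seed optional seed stored in the config.
#' @return a `model_config`.
#' @export
referential_set <- function(..., N_f = 2, N_b = 2, n_gamma = 500,
                            seed = NULL) {
  model_config(
    forward = motor_species(polarity = +1, count = N_f, ...),
    backward = motor_species(polarity = -1, count = N_b, ...),
    env = transport_env(n_gamma = n_gamma),
    seed = seed)
}

#' Parameter-scaling transformation
#'
#' Applies the approximate dynamical invariance `Fs -> lambda Fs`,
#' `Fd -> beta Fd`, `k -> lambda k`, `gamma -> lambda gamma` (implemented by
#' scaling `n_gamma`), which maps a configuration onto a scaled system with
#' similar dynamics. `beta` is expected to be of order `sqrt(lambda)`.
#'
#' @param cfg a `model_config`.
#' @param lam scale factor `lambda` (> 0); the transformation is validated
#'   for `0.4 < lambda <= 1`, values outside that window warn.
#' @param beta detachment-force scale factor; warns when it departs from
#'   `sqrt(lambda)` by more than 30%.
#' @return the scaled `model_config`.
#' @export
scale_parameters <- function(cfg, lam, beta) {
  if (!is.numeric(lam) || lam <= 0) stop("lam must be > 0", call. = FALSE)
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (lam <= 0.4 || lam > 1)
    warning("lam outside the validated window (0.4, 1]")
  if (abs(beta - sqrt(lam)) / sqrt(lam) > 0.3)
    warning("beta departs from sqrt(lam) by more than 30%")
  scale_team <- function(sp) {
    sp$Fs <- lam * sp$Fs
    sp$Fd <- beta * sp$Fd
    sp$k <- lam * sp$k
    sp
  }
  cfg$forward <- scale_team(cfg$forward)
  cfg$backward <- scale_team(cfg$backward)
  cfg$env <- transport_env(n_gamma = lam * cfg$env$n_gamma,
                           r = cfg$env$r, T = cfg$env$T)
  cfg
}

#' @export
print.model_config <- function(x, ...) {
  cat("tug-of-war model_config\n")
  cat(sprintf("  teams: N_f = %d, N_b = %d\n",
              x$forward$count, x$backward$count))
  fmt <- function(sp) sprintf(
    "v0=%g nm/s Fs=%g pN w=%g eps=%g/s Fd=%g pN pi=%g/s k=%g pN/nm x0=%g nm",
    sp$v0, sp$Fs, sp$w, sp$eps, sp$Fd, sp$pi_att, sp$k, sp$x0)
  cat("  forward: ", fmt(x$forward), "\n")
  cat("  backward:", fmt(x$backward), "\n")
  cat(sprintf("  env: n_gamma=%g r=%g nm T=%g K (gamma=%.4g pN s/nm)\n",
              x$env$n_gamma, x$env$r, x$env$T, x$env$gamma))
  cat(sprintf("  numerics: dt=%g s, sample_dt=%g s, t_max=%g s\n",
              x$dt, x$sample_dt, x$t_max))
  invisible(x)
}
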