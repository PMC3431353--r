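# Canonical study conditions and the streaming simulate -> analyze driver.

#' Canonical parameter sets of the melanosome transport study
#'
#' Named configurations used throughout the package:
#' \describe{
#'   \item{`rs`}{the symmetric referential set ([referential_set()]).}
#'   \item{`stiff`}{RS with stiff motor linkers, `k = 0.3` pN/nm (the
#'     in-vitro kinesin stiffness); produces unimodal velocity
#'     distributions and abrupt reversions.}
#'   \item{`set1`}{dispersion-like asymmetric set: `pi_f = 3.5/s`,
#'     `pi_b = 2.2/s`, `eps_f = 0.08/s`, `eps_b = 0.07/s`,
#'     `n_gamma = 300`, rest as RS.}
#'   \item{`set2`}{aggregation-like asymmetric set: `pi_f = 1.8/s`,
#'     `pi_b = 2.2/s`, `eps_f = eps_b = 0.08/s`, `n_gamma = 300`.}
#'   \item{`imbalanced`}{RS with one extra backward motor
#'     (`N_f = 2, N_b = 3`); drives ~98% backward segments.}
#' }
#'
#' @param name one of `"rs"`, `"stiff"`, `"set1"`, `"set2"`,
#'   `"imbalanced"`.
#' @return a `model_config`.
#' @export
canonical_config <- function(name = c("rs", "stiff", "set1", "set2",
                                      "imbalanced")) {
  name <- match.arg(name)
  switch(name,
    rs = referential_set(),
    stiff = referential_set(k = 0.3),
    set1 = model_config(
      forward = motor_species(+1, 2, eps = 0.08, pi_att = 3.5),
      backward = motor_species(-1, 2, eps = 0.07, pi_att = 2.2),
      env = transport_env(n_gamma = 300)),
    set2 = model_config(
      forward = motor_species(+1, 2, eps = 0.08, pi_att = 1.8),
      backward = motor_species(-1, 2, eps = 0.08, pi_att = 2.2),
      env = transport_env(n_gamma = 300)),
    imbalanced = referential_set(N_f = 2, N_b = 3))
}

#' Simulate an ensemble and analyze it on the fly
#'
#' Streams trajectories one at a time (memory stays flat in the ensemble
#' size): each trajectory is simulated, segmented and analyzed, then
#' discarded, keeping only segments, reversion events and pooled spatial
#' counts.
#'
#' @param cfg a `model_config`.
#' @param n_traj ensemble size.
#' @param base_seed seed for the ensemble (per-trajectory streams are
#'   derived deterministically).
#' @param windows optional named list of `c(vmin, vmax)` velocity windows
#'   (nm/s) for spatial motor distributions / mu.
#' @param reversions detect and fit long-term reversions.
#' @param progress print a progress line every 100 trajectories.
#' @param ... threshold overrides passed to the analysis functions
#'   ([select_processive_periods()], [extract_segments()],
#'   [detect_reversions()], [fit_rise_time()]).
#' @return list with `segments` (a combined `segment_set`), `spatial`
#'   (per-window results incl. `mu`), `reversions` (event table),
#'   `termination` (tally of termination reasons), `n_traj`, `base_seed`.
#' @export
analyze_ensemble <- function(cfg, n_traj, base_seed, windows = NULL,
                             reversions = FALSE, progress = FALSE, ...) {
  dots <- list(...)
  pick <- function(fn) dots[names(dots) %in% names(formals(fn))]
  accs <- lapply(windows %||% list(), spatial_accumulator)
  segsets <- vector("list", n_traj)
  rev_rows <- list()
  term <- c(t_max = 0L, full_detach = 0L)
  for (i in seq_len(n_traj)) {
    traj <- simulate(cfg, seed = base_seed, stream = i - 1L)
    term[traj$termination] <- term[traj$termination] + 1L
    iv <- do.call(select_processive_periods,
                  c(list(traj), pick(select_processive_periods)))
    ss <- do.call(extract_segments,
                  c(list(traj, iv), pick(extract_segments)))
    segsets[[i]] <- ss
    for (wi in seq_along(accs))
      accs[[wi]] <- spatial_accumulate(accs[[wi]], traj, ss)
    if (reversions) {
      evs <- do.call(detect_reversions,
                     c(list(traj), pick(detect_reversions)))
      for (ev in evs) {
        ev <- do.call(fit_rise_time, c(list(ev, traj), pick(fit_rise_time)))
        rev_rows[[length(rev_rows) + 1]] <- data.frame(
          traj = i, t_rev = ev$t_rev, direction = ev$direction,
          back_displacement = ev$back_displacement,
          back_duration = ev$back_duration,
          t_r_ms = if (isTRUE(ev$fitted)) ev$t_r_ms else NA_real_,
          A = if (isTRUE(ev$fitted)) ev$A else NA_real_,
          fitted = isTRUE(ev$fitted), flag = ev$flag %||% "ok")
      }
    }
    if (progress && i %% 100 == 0)
      message(sprintf("[tugsim] %d/%d trajectories", i, n_traj))
  }
  list(segments = combine_segment_sets(segsets),
       spatial = lapply(accs, spatial_finalize),
       reversions = if (reversions && length(rev_rows) > 0)
         do.call(rbind, rev_rows) else NULL,
       termination = term, n_traj = n_traj, base_seed = base_seed)
}

#' Run a named reproduction recipe
#'
#' Executes a full simulate-and-analyze chain with the documented study
#' conditions and, when `out_dir` is given, writes the result tables as
#' CSV plus a JSON run manifest.
#'
#' \describe{
#'   \item{`rs_histogram`}{RS ensemble; forward-branch segmental-velocity
#'     histogram and its four-Gaussian fit.}
#'   \item{`stiff_histogram`}{same for the stiff-linker (`k = 0.3`)
#'     system.}
#'   \item{`spatial_mu`}{RS mu for velocity regions I (100-300 nm/s),
#'     II (350-550) and III (700-900), plus the stiff system in
#'     300-500 nm/s.}
#'   \item{`reversion_tr`}{characteristic rise times for RS and stiff
#'     ensembles.}
#'   \item{`aggregation_dispersion`}{Set 1 / Set 2 backward-segment
#'     percentages and backward-branch A2/A1 ratios.}
#' }
#'
#' @param recipe recipe name (see Details).
#' @param n_traj trajectories per ensemble.
#' @param base_seed ensemble seed.
#' @param config optional `model_config` override for single-ensemble
#'   recipes (defaults to the recipe's canonical configuration).
#' @param out_dir optional output directory for CSV tables + manifest.
#' @return list with recipe-specific results and the `run_manifest`.
#' @export
run_experiment <- function(recipe = c("rs_histogram", "stiff_histogram",
                                      "spatial_mu", "reversion_tr",
                                      "aggregation_dispersion"),
                           n_traj = 500, base_seed = 1, config = NULL,
                           out_dir = NULL) {
  recipe <- match.arg(recipe)
  man <- new_manifest(paste("recipe:", recipe))
  res <- switch(recipe,
    rs_histogram = ,
    stiff_histogram = {
      cfg <- config %||% canonical_config(
        if (recipe == "rs_histogram") "rs" else "stiff")
      ens <- analyze_ensemble(cfg, n_traj, base_seed)
      hist <- velocity_histogram(ens$segments, direction = "forward")
      fit <- tryCatch(fit_four_gaussians(hist), error = function(e) NULL)
      list(config = cfg, segments = ens$segments, histogram = hist,
           fit = fit, termination = ens$termination)
    },
    spatial_mu = {
      wins <- list(I = c(100, 300), II = c(350, 550), III = c(700, 900))
      rs <- analyze_ensemble(config %||% canonical_config("rs"), n_traj,
                             base_seed, windows = wins)
      stiff <- analyze_ensemble(canonical_config("stiff"), n_traj,
                                base_seed + 1,
                                windows = list(stiff = c(300, 500)))
      mu <- data.frame(
        system = c("rs", "rs", "rs", "stiff"),
        region = c("I", "II", "III", "300-500"),
        vmin = c(100, 350, 700, 300), vmax = c(300, 550, 900, 500),
        mu = c(vapply(rs$spatial, `[[`, 0, "mu"),
               stiff$spatial$stiff$mu))
      list(mu_table = mu, rs = rs$spatial, stiff = stiff$spatial$stiff)
    },
    reversion_tr = {
      rs <- analyze_ensemble(config %||% canonical_config("rs"), n_traj,
                             base_seed, reversions = TRUE)
      stiff <- analyze_ensemble(canonical_config("stiff"), n_traj,
                                base_seed + 1, reversions = TRUE)
      list(rs_events = rs$reversions,
           stiff_events = stiff$reversions,
           rs_t_r = rise_time_statistics(rs$reversions$t_r_ms),
           stiff_t_r = rise_time_statistics(stiff$reversions$t_r_ms))
    },
    aggregation_dispersion = {
      summarize_set <- function(name, seed_off) {
        ens <- analyze_ensemble(canonical_config(name), n_traj,
                                base_seed + seed_off)
        hist_b <- velocity_histogram(ens$segments, direction = "backward")
        fit <- tryCatch(fit_four_gaussians(hist_b), error = function(e) NULL)
        a21 <- if (is.null(fit)) list(ratio = NA, se = NA)
               else amplitude_ratio(fit, 2, 1)
        list(backward_pct = 100 * backward_fraction(ens$segments),
             a2_a1_backward = a21$ratio, a2_a1_se = a21$se,
             histogram = hist_b, fit = fit, segments = ens$segments)
      }
      s1 <- summarize_set("set1", 0)
      s2 <- summarize_set("set2", 1)
      tab <- data.frame(
        set = c("set1", "set2"),
        backward_pct = c(s1$backward_pct, s2$backward_pct),
        a2_a1_backward = c(s1$a2_a1_backward, s2$a2_a1_backward))
      list(table = tab, set1 = s1, set2 = s2)
    })
  man <- manifest_add(man, recipe,
                      params = list(n_traj = n_traj, base_seed = base_seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    outs <- character(0)
    save_df <- function(df, name) {
      p <- file.path(out_dir, paste0(name, ".csv"))
      utils::write.csv(df, p, row.names = FALSE)
      outs <<- c(outs, p)
    }
    if (!is.null(res$segments)) save_df(res$segments$segments, "segments")
    if (!is.null(res$histogram))
      save_df(data.frame(mid = res$histogram$mids,
                         weight = res$histogram$weights), "histogram")
    if (!is.null(res$mu_table)) save_df(res$mu_table, "mu")
    if (!is.null(res$table)) save_df(res$table, "aggregation_dispersion")
    if (!is.null(res$rs_events)) save_df(res$rs_events, "reversions_rs")
    if (!is.null(res$stiff_events))
      save_df(res$stiff_events, "reversions_stiff")
    man <- manifest_add(man, "outputs", outputs = outs)
    write_manifest(man, file.path(out_dir, "manifest.json"))
  }
  res$manifest <- man
  res
}
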