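# Configuration files, trajectory tables and run manifests.
#
# Configs are flat YAML documents mirroring model_config (units as in the
# constructors: nm, s, pN, pN/nm, 1/s, K). Trajectories are stored as CSV
# (UTF-8, '.' decimal, header row; time in s, positions in nm) with a JSON
# metadata sidecar holding config, seed and termination reason.

config_to_list <- function(cfg) {
  team <- function(sp) sp[c("polarity", "count", "v0", "Fs", "w", "eps",
                            "Fd", "pi_att", "k", "x0", "dx")]
  list(forward = team(cfg$forward), backward = team(cfg$backward),
       env = cfg$env[c("n_gamma", "r", "T")],
       dt = cfg$dt, t_max = cfg$t_max, sample_dt = cfg$sample_dt,
       seed = cfg$seed, stop_on_full_detach = cfg$stop_on_full_detach,
       noise = cfg$noise)
}

list_to_config <- function(lst) {
  need <- function(block, key, where) {
    if (is.null(block[[key]]))
      stop("config is missing key '", where, ".", key, "'", call. = FALSE)
    block[[key]]
  }
  team <- function(block, where) {
    args <- lapply(c("polarity", "count", "v0", "Fs", "w", "eps", "Fd",
                     "pi_att", "k", "x0", "dx"),
                   function(k) need(block, k, where))
    names(args) <- c("polarity", "count", "v0", "Fs", "w", "eps", "Fd",
                     "pi_att", "k", "x0", "dx")
    do.call(motor_species, args)
  }
  env <- transport_env(n_gamma = need(lst$env, "n_gamma", "env"),
                       r = need(lst$env, "r", "env"),
                       T = need(lst$env, "T", "env"))
  model_config(forward = team(lst$forward, "forward"),
               backward = team(lst$backward, "backward"),
               env = env,
               dt = lst$dt %||% 1e-5, t_max = lst$t_max %||% 20,
               sample_dt = lst$sample_dt %||% 0.01, seed = lst$seed,
               stop_on_full_detach = lst$stop_on_full_detach %||% TRUE,
               noise = lst$noise %||% TRUE)
}

#' Write a model configuration to a YAML file
#' @param cfg a `model_config`.
#' @param path output file path.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(config_to_list(cfg), path)
  invisible(path)
}

#' Read and validate a model configuration from YAML
#'
#' Validation failures name the offending key.
#' @param path path to a YAML config written by [write_config()] (or by
#'   hand, with the same flat layout).
#' @return a validated `model_config`.
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  list_to_config(lst)
}

#' Write a trajectory as CSV plus JSON metadata sidecar
#'
#' @param traj a `cargo_trajectory`.
#' @param path CSV output path; metadata goes to `<path>.meta.json`.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(config = config_to_list(traj$config), seed = traj$seed,
               stream = traj$stream, dt_used = traj$dt_used,
               termination = traj$termination)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_csv()]
#'
#' Plain two-column (t, x) CSVs from external tracking software are also
#' accepted; motor-state channels are then unavailable.
#' @param path CSV path.
#' @return a `cargo_trajectory` (full state channels when the file carries
#'   them) or a (t, x) data frame for plain tabular input.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t", "x_c", "nf", "nb", "qf", "qb") %in% names(df)))
    return(df[, 1:2])
  att_cols <- grep("^m[0-9]+_att$", names(df), value = TRUE)
  x_cols <- grep("^m[0-9]+_x$", names(df), value = TRUE)
  meta_path <- paste0(path, ".meta.json")
  config <- NULL; seed <- NA; stream <- NA; term <- NA; dt_used <- NA
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    config <- list_to_config(meta$config)
    seed <- meta$seed; stream <- meta$stream
    term <- meta$termination; dt_used <- meta$dt_used
  }
  traj <- list(t = df$t, x_c = df$x_c,
               attached = as.matrix(df[, att_cols, drop = FALSE]) == 1 |
                 as.matrix(df[, att_cols, drop = FALSE]) == TRUE,
               x_m = as.matrix(df[, x_cols, drop = FALSE]),
               nf = df$nf, nb = df$nb, qf = df$qf, qb = df$qb,
               config = config, seed = seed, stream = stream,
               dt_used = dt_used, termination = term)
  class(traj) <- "cargo_trajectory"
  traj
}

#' Create an empty run manifest
#'
#' A manifest records, per pipeline stage, the inputs, outputs (with MD5
#' checksums), parameters, seeds and timestamps, so every analysis output
#' is traceable to the run that produced it.
#' @param label free-text run label.
#' @return an object of class `run_manifest`.
#' @export
new_manifest <- function(label = "tugsim run") {
  structure(list(label = label,
                 tool_version = as.character(utils::packageVersion("tugsim")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 stages = list()),
            class = "run_manifest")
}

#' Record a pipeline stage in a manifest
#' @param manifest a `run_manifest`.
#' @param stage stage name.
#' @param params named list of stage parameters (seeds included).
#' @param inputs,outputs character vectors of file paths; existing files
#'   are checksummed.
#' @export
manifest_add <- function(manifest, stage, params = list(),
                         inputs = character(0), outputs = character(0)) {
  sums <- function(paths) {
    ok <- file.exists(paths)
    md5 <- rep(NA_character_, length(paths))
    md5[ok] <- unname(tools::md5sum(paths[ok]))
    if (length(paths)) stats::setNames(as.list(md5), paths) else list()
  }
  manifest$stages[[stage]] <- list(params = params,
                                   inputs = sums(inputs),
                                   outputs = sums(outputs),
                                   time = format(Sys.time(),
                                                 "%Y-%m-%dT%H:%M:%S%z"))
  manifest
}

#' Write a manifest as JSON
#' @param manifest a `run_manifest`.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
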