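#' Read a trajectory table
#'
#' Reads the package's comma-delimited trajectory dialect: mandatory header
#' `trajectory_id,time,n`, one row per observation, times sorted within each
#' trajectory. This is the calibration input format.
#'
#' @param path file path.
#' @param N optional number of agents; states are validated against it.
#' @return Data frame with columns `trajectory_id`, `time`, `n`.
#' @export
read_trajectories <- function(path, N = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "trajectory_id,time,n"))
    stop("expected header 'trajectory_id,time,n' in ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no trajectories in ", path)
  bad <- which(!is.finite(df$n) | df$n != round(df$n) | df$n < 0)
  if (length(bad))
    stop(sprintf("non-integer or negative state at line %d", bad[1] + 1L))
  if (!is.null(N)) {
    bad <- which(df$n > N)
    if (length(bad))
      stop(sprintf("state exceeds N = %d at line %d", N, bad[1] + 1L))
  }
  for (part in split(seq_len(nrow(df)), df$trajectory_id)) {
    tt <- df$time[part]
    if (is.unsorted(tt, strictly = FALSE))
      stop(sprintf("unsorted times in trajectory '%s' near line %d",
                   df$trajectory_id[part[1]],
                   part[which(diff(tt) < 0)[1] + 1L] + 1L))
  }
  df$n <- as.integer(df$n)
  df
}

#' Write a trajectory table
#'
#' @param data data frame with columns `trajectory_id`, `time`, `n`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(data, path) {
  stopifnot(all(c("trajectory_id", "time", "n") %in% names(data)))
  write.csv(data[c("trajectory_id", "time", "n")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write a distribution over states
#'
#' Three-column CSV: `n`, `m`, `probability`.
#'
#' @param dist a `bd_distribution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "bd_distribution"))
  write.csv(as.data.frame(dist), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a distribution written by [write_distribution()]
#'
#' @param path file path.
#' @return A `bd_distribution`.
#' @export
read_distribution <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("n", "probability") %in% names(df)))
  N <- max(df$n)
  p <- numeric(N + 1)
  p[df$n + 1] <- df$probability
  finalise_distribution(p, list(N = N))
}

#' Read and validate a run configuration
#'
#' YAML configuration with a `model` block (rate `family` plus the model
#' parameters) and a `task` block naming exactly one task (`solve`, `steady`,
#' `spectrum`, `simulate`, `passage`, `calibrate`, `fixtures` or
#' `experiment`) with its task-specific settings. Because bare `F` and `N`
#' are YAML 1.1 booleans, the schema spells them out: `field` for the
#' exogenous field and `agents` for the population size (alongside `J`,
#' `alpha`, `beta`, `gamma`, and `epsilon`/`mu` for the Kirman family).
#' Numeric tolerances and seeds default as in the corresponding functions.
#'
#' @param path YAML file path.
#' @return A validated list with elements `model` (a parameter object),
#'   `task` (character) and `settings` (list).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config must contain a 'model' block")
  task <- if (is.list(cfg$task)) cfg$task$name else cfg$task
  if (is.null(task) || length(task) != 1)
    stop("config must name exactly one task")
  fam <- cfg$model$family %||% "logit"
  mp <- cfg$model
  mp$family <- NULL
  rename <- c(field = "F", agents = "N",
              self_interaction = "include_self_interaction")
  for (k in names(rename))
    if (!is.null(mp[[k]])) {
      mp[[rename[[k]]]] <- mp[[k]]
      mp[[k]] <- NULL
    }
  model <- if (fam == "kirman") {
    do.call(kirman_params, mp)
  } else {
    do.call(model_params, mp)
  }
  tasks <- c("solve", "steady", "spectrum", "simulate", "passage",
             "calibrate", "fixtures", "experiment")
  if (!task %in% tasks)
    stop("unknown task '", task, "'; expected one of: ",
         paste(tasks, collapse = ", "))
  settings <- if (is.list(cfg$task)) cfg$task[setdiff(names(cfg$task), "name")] else list()
  list(model = model, family = fam, task = task, settings = settings,
       seed = cfg$seed %||% 1L, out = cfg$out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fixture presets reproducing the published parameter sets
#'
#' Named presets used throughout the package's examples and tests:
#' `fig1` (`F = 0, J = 10, alpha = 0, beta = 1, gamma = 1, N = 100`,
#' `n0 = 50`, 2500 trajectories on a short grid), `fig2`
#' (`F = 0.1, J = 5, N = 50`, `n0 = 25`), `fig3`
#' (`F = 0.025, J = 1.5, N = 50`, `n0 = 25`), and `calibration` (the `fig3`
#' parameter set as calibration truth: 200 trajectories observed at 100
#' points on `[0, 2000]`).
#'
#' @param name preset name; omit to list all presets.
#' @return The preset definition (list), or a character vector of names.
#' @export
fixture_presets <- function(name = NULL) {
  presets <- list(
    fig1 = list(params = model_params(F = 0, J = 10, alpha = 0, beta = 1,
                                      gamma = 1, N = 100),
                n0 = 50, grid = seq(0.1, 2, by = 0.1), n_traj = 2500),
    fig2 = list(params = model_params(F = 0.1, J = 5, alpha = 0, beta = 1,
                                      gamma = 1, N = 50),
                n0 = 25, grid = seq(0.5, 50, by = 0.5), n_traj = 100),
    fig3 = list(params = model_params(F = 0.025, J = 1.5, alpha = 0, beta = 1,
                                      gamma = 1, N = 50),
                n0 = 25, grid = seq(20, 2000, by = 20), n_traj = 100),
    calibration = list(params = model_params(F = 0.025, J = 1.5, alpha = 0,
                                             beta = 1, gamma = 1, N = 50),
                       n0 = 25, grid = seq(20, 2000, by = 20), n_traj = 200)
  )
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Generate a deterministic synthetic fixture dataset
#'
#' Simulates SSA trajectories for a named preset, samples them on the preset
#' grid and writes `trajectories.csv` plus a `metadata.yaml` sidecar
#' recording the parameters, grid and seed. Byte-identical for a fixed seed.
#'
#' @param preset_name one of [fixture_presets()].
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @param n_traj optional override of the preset trajectory count.
#' @return Named character vector of the files written, invisibly; the
#'   trajectory table is also returned as attribute `"data"`.
#' @export
generate_fixture <- function(preset_name, seed = 1, out_dir = ".",
                             n_traj = NULL) {
  preset <- fixture_presets(preset_name)
  if (!is.null(n_traj)) preset$n_traj <- n_traj
  rates <- propensities(preset$params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- lapply(seq_len(preset$n_traj), function(i) {
    tr <- ssa_trajectory(rates, preset$n0, max(preset$grid),
                         seed = derive_seed(seed, i))
    data.frame(trajectory_id = i, time = c(0, preset$grid),
               n = c(preset$n0, sample_on_grid(tr, preset$grid)))
  })
  data <- do.call(rbind, tabs)
  traj_path <- file.path(out_dir, "trajectories.csv")
  meta_path <- file.path(out_dir, "metadata.yaml")
  write_trajectories(data, traj_path)
  p <- preset$params
  yaml::write_yaml(list(
    preset = preset_name, seed = seed, n_traj = preset$n_traj, n0 = preset$n0,
    grid = list(from = min(preset$grid), to = max(preset$grid),
                points = length(preset$grid)),
    params = list(field = p$F, J = p$J, alpha = p$alpha, beta = p$beta,
                  gamma = p$gamma, agents = p$N)), meta_path)
  out <- c(trajectories = traj_path, metadata = meta_path)
  attr(out, "data") <- data
  invisible(out)
}

#' Write a passage report as key-value delimited text
#'
#' @param passage a [passage_analysis()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_passage_report <- function(passage, path) {
  stopifnot(inherits(passage, "bd_passage"))
  s <- passage$structure
  kv <- c(n_minus = s$n_minus, n_u = s$n_u, n_plus = s$n_plus,
          phi_R = passage$phi_R, tau_lr = passage$tau_lr,
          tau_rl = passage$tau_rl, lambda2_approx = passage$lambda2_approx,
          relaxation_time_approx = passage$relaxation_time_approx,
          pi_L_s = passage$pi_L_s, pi_R_s = passage$pi_R_s)
  write.csv(data.frame(key = names(kv), value = unname(kv)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
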