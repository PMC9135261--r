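#' Composite negative log-likelihood of observed trajectories
#'
#' The likelihood of a trajectory observed at times `t_i` is the product of
#' marginal probabilities `P_theta(n_i, t_i | n0, 0)` from the exact transient
#' solution (a composite likelihood over marginals given the known initial
#' condition, not a Markov transition product). One spectral decomposition per
#' parameter set is reused across all time points and trajectories, and
#' probabilities are floored at `1e-300` before taking logs.
#'
#' Because `beta` multiplies `F` and `J` (and `1 + alpha` multiplies `beta J`)
#' in the gain, only `beta F` and `beta (1 + alpha) J` are identifiable; the
#' likelihood is exactly constant along that scaling direction.
#'
#' @param data trajectory table: data frame with columns `trajectory_id`,
#'   `time`, `n` (the dialect of [read_trajectories()]).
#' @param theta numeric vector `c(F, J, gamma)` (or a named list).
#' @param N number of agents.
#' @param beta,alpha fixed during calibration (defaults 1 and 0).
#' @param n0 initial state. `NULL` applies the default policy: an observation
#'   at `t = 0` is treated as the exact initial condition of its trajectory
#'   (contributing probability 1); trajectories without one are an error.
#' @return The negative log-likelihood (scalar; `+Inf` if any observation has
#'   zero floored probability).
#' @export
negative_log_likelihood <- function(data, theta, N, beta = 1, alpha = 0,
                                    n0 = NULL) {
  obs <- normalise_observations(data, N, n0)
  nll_core(obs, theta, N, beta, alpha)
}

# Likelihood kernel on pre-normalised observation groups; calibrate() calls
# this directly so the observation table is only parsed once per search.
nll_core <- function(obs, theta, N, beta, alpha) {
  theta <- unlist(theta)[1:3]
  params <- model_params(F = theta[1], J = theta[2], alpha = alpha,
                         beta = beta, gamma = theta[3], N = N)
  rates <- propensities(params)
  cache <- spectral_cache(rates)
  nll <- 0
  for (g in obs) {
    if (length(g$times) == 0) next  # only the t = 0 point: P = 1 exactly
    P <- transient_probs_cached(cache, g$n0, g$times)
    nll <- nll - sum(g$counts * log(pmax(P, 1e-300)))
  }
  nll
}

# Splits the trajectory table by initial state; returns a list of groups,
# each with fields n0, time, n (t > 0 observations only).
normalise_observations <- function(data, N, n0 = NULL) {
  stopifnot(is.data.frame(data),
            all(c("trajectory_id", "time", "n") %in% names(data)))
  if (any(data$n < 0 | data$n > N | data$n != round(data$n)))
    stop("observations must be integers in [0, N]")
  parts <- split(data, data$trajectory_id)
  recs <- lapply(parts, function(d) {
    d <- d[order(d$time), ]
    if (is.null(n0)) {
      if (d$time[1] != 0)
        stop("no t = 0 observation to serve as initial condition; supply n0")
      list(n0 = d$n[1], time = d$time[-1], n = d$n[-1])
    } else {
      keep <- d$time > 0
      list(n0 = n0, time = d$time[keep], n = d$n[keep])
    }
  })
  # merge trajectories sharing an initial state so the spectral work is
  # shared, and aggregate observations into per-(state, time) counts
  by_n0 <- split(recs, vapply(recs, `[[`, numeric(1), "n0"))
  lapply(by_n0, function(rs) {
    time <- unlist(lapply(rs, `[[`, "time"))
    n <- as.integer(unlist(lapply(rs, `[[`, "n")))
    times <- sort(unique(time))
    counts <- matrix(0, N + 1, length(times))
    idx <- cbind(n + 1L, match(time, times))
    for (r in seq_len(nrow(idx)))
      counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + 1
    list(n0 = rs[[1]]$n0, times = times, counts = counts)
  })
}

#' Define a calibration problem
#'
#' Bundles the data, the known model dimensions and the search box for
#' [calibrate()]. `F` is searched linearly; `J` and `gamma` in log-space,
#' inside the default box `F` in `[-2, 2]`, `J` in `[e^-2, e^2]`, `gamma` in
#' `[e^-1, e^1]`. `beta` and `alpha` are fixed (they are not identifiable
#' jointly with `F` and `J`).
#'
#' @param data trajectory table (columns `trajectory_id`, `time`, `n`).
#' @param N number of agents.
#' @param n0 known initial state, or `NULL` to take each trajectory's `t = 0`
#'   observation.
#' @param F_range linear bounds on `F`.
#' @param logJ_range,loggamma_range bounds on `log J` and `log gamma`.
#' @param beta,alpha fixed values.
#' @param population,generations,seed differential-evolution settings.
#' @return A `bd_calibration_problem` list.
#' @export
calibration_problem <- function(data, N, n0 = NULL,
                                F_range = c(-2, 2),
                                logJ_range = c(-2, 2),
                                loggamma_range = c(-1, 1),
                                beta = 1, alpha = 0,
                                population = 50, generations = 150,
                                seed = 1) {
  stopifnot(population >= 4, generations >= 1)
  structure(list(data = data, N = N, n0 = n0, F_range = F_range,
                 logJ_range = logJ_range, loggamma_range = loggamma_range,
                 beta = beta, alpha = alpha, population = population,
                 generations = generations, seed = seed),
            class = "bd_calibration_problem")
}

# Classic differential evolution (rand/1/bin) on a box; seeded, greedy
# selection, returns best point and a per-generation trace of the best value.
de_optimise <- function(fn, lower, upper, population, generations, seed,
                        f_mut = 0.8, cr = 0.9) {
  set.seed(seed)
  d <- length(lower)
  pop <- matrix(runif(population * d, lower, upper), population, d, byrow = TRUE)
  val <- apply(pop, 1, fn)
  trace <- numeric(generations)
  for (gen in seq_len(generations)) {
    for (i in seq_len(population)) {
      r <- sample(setdiff(seq_len(population), i), 3)
      mut <- pop[r[1], ] + f_mut * (pop[r[2], ] - pop[r[3], ])
      mut <- pmin(pmax(mut, lower), upper)
      cross <- runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      cand <- ifelse(cross, mut, pop[i, ])
      v <- fn(cand)
      if (v <= val[i]) {
        pop[i, ] <- cand
        val[i] <- v
      }
    }
    trace[gen] <- min(val)
  }
  best <- which.min(val)
  list(par = pop[best, ], value = val[best], trace = trace)
}

#' Calibrate model parameters by differential evolution
#'
#' Global search for `theta* = argmin -log L` over `(F, log J, log gamma)`
#' inside the problem's box, using a seeded differential-evolution optimiser.
#' The result is a good local minimum of the (multimodal) negative
#' log-likelihood, not a certified global optimum.
#'
#' @param problem a [calibration_problem()].
#' @return An object of class `bd_calibration`: `theta_star` (named vector
#'   `F`, `J`, `gamma`), `nll_star`, and the optimiser `trace`.
#' @export
calibrate <- function(problem) {
  stopifnot(inherits(problem, "bd_calibration_problem"))
  obs <- normalise_observations(problem$data, problem$N, problem$n0)
  obj <- function(x) {
    nll_core(obs, c(x[1], exp(x[2]), exp(x[3])),
             N = problem$N, beta = problem$beta, alpha = problem$alpha)
  }
  lower <- c(problem$F_range[1], problem$logJ_range[1], problem$loggamma_range[1])
  upper <- c(problem$F_range[2], problem$logJ_range[2], problem$loggamma_range[2])
  fit <- de_optimise(obj, lower, upper, problem$population,
                     problem$generations, problem$seed)
  theta <- c(F = fit$par[1], J = exp(fit$par[2]), gamma = exp(fit$par[3]))
  structure(list(theta_star = theta, nll_star = fit$value, trace = fit$trace,
                 problem = problem),
            class = "bd_calibration")
}

#' @export
print.bd_calibration <- function(x, ...) {
  cat(sprintf("Calibration: F* = %.4g, J* = %.4g, gamma* = %.4g (NLL = %.4f)\n",
              x$theta_star["F"], x$theta_star["J"], x$theta_star["gamma"],
              x$nll_star))
  invisible(x)
}

#' Calibration error metrics
#'
#' `E_tot = sum_i |(theta_true_i - theta*_i) / theta_true_i|` over
#' `{F, J, gamma}`, and `f = |((F/J)_true - F*/J*) / (F/J)_true|`, the error
#' on the exogenous-to-endogenous ratio.
#'
#' @param theta_true,theta_star numeric vectors `c(F, J, gamma)` (named or
#'   positional); all true components must be non-zero.
#' @return Named vector `c(E_tot, f)`.
#' @export
calibration_errors <- function(theta_true, theta_star) {
  tt <- unlist(theta_true)[1:3]
  ts <- unlist(theta_star)[1:3]
  if (any(tt == 0)) stop("theta_true components must be non-zero")
  E_tot <- sum(abs((tt - ts) / tt))
  ratio_true <- tt[1] / tt[2]
  f <- abs((ratio_true - ts[1] / ts[2]) / ratio_true)
  c(E_tot = unname(E_tot), f = unname(f))
}

#' Data-requirement experiments for calibration
#'
#' Runs the three calibration protocols on synthetic SSA data at a true
#' parameter set: (i) a single trajectory confined to one mode, calibrated
#' over increasing horizons; (ii) a single trajectory that explores both
#' modes, over increasing horizons and varying numbers of observation points;
#' (iii) growing numbers of independent realisations. Tabulates `E_tot` and
#' `f` per condition. Mode exploration is judged by whether the trajectory
#' crosses the unstable point `n_u` after first committing to a mode.
#'
#' @param config list of settings; unset entries take the defaults:
#'   `theta_true = c(F = 0.025, J = 1.5, gamma = 1)`, `N = 50`, `n0 = 25`,
#'   `horizon = 2000`, `n_points = 100`, `horizons = c(250, 500, 1000, 2000)`,
#'   `points_grid = c(10, 32, 100, 316, 1001)`,
#'   `counts = c(1, 11, 101, 1001)`, `population = 50`, `generations = 150`,
#'   `seed = 1`, `max_tries = 200` (search attempts for the protocol (i)/(ii)
#'   trajectories).
#' @return Data frame with columns `protocol`, `condition`, `value` (the
#'   varied quantity), `E_tot`, `f`, `nll_star`, `seed`.
#' @export
experiment_data_requirements <- function(config = list()) {
  cfg <- utils::modifyList(list(
    theta_true = c(F = 0.025, J = 1.5, gamma = 1),
    N = 50, n0 = 25, horizon = 2000, n_points = 100,
    horizons = c(250, 500, 1000, 2000),
    points_grid = c(10, 32, 100, 316, 1001),
    counts = c(1, 11, 101, 1001),
    population = 50, generations = 150, seed = 1, max_tries = 200
  ), config)
  th <- cfg$theta_true
  params <- model_params(F = th[1], J = th[2], gamma = th[3], N = cfg$N)
  rates <- propensities(params)
  nu <- find_unstable_point(steady_state(rates))$n_u
  grid <- seq(0, cfg$horizon, length.out = cfg$n_points + 1)[-1]

  crosses_both <- function(states) {
    committed <- states > nu + 2 | states < nu - 2
    if (!any(committed)) return(FALSE)
    side <- sign(states[committed][1] - nu)
    any(sign(states[committed] - nu) == -side)
  }
  find_traj <- function(both, seed0) {
    for (k in seq_len(cfg$max_tries)) {
      tr <- ssa_trajectory(rates, cfg$n0, cfg$horizon,
                           seed = derive_seed(seed0, k))
      s <- sample_on_grid(tr, grid)
      if (crosses_both(s) == both) return(tr)
    }
    stop("could not find a trajectory with the requested mode coverage")
  }
  as_table <- function(tr, times) {
    data.frame(trajectory_id = 1L,
               time = c(0, times),
               n = c(cfg$n0, sample_on_grid(tr, times)))
  }
  run_one <- function(data, seed) {
    prob <- calibration_problem(data, N = cfg$N, n0 = NULL,
                                population = cfg$population,
                                generations = cfg$generations, seed = seed)
    fit <- calibrate(prob)
    err <- calibration_errors(th, fit$theta_star)
    c(err, nll_star = fit$nll_star)
  }

  rows <- list()
  add <- function(protocol, condition, value, res, seed) {
    rows[[length(rows) + 1]] <<- data.frame(
      protocol = protocol, condition = condition, value = value,
      E_tot = res[["E_tot"]], f = res[["f"]], nll_star = res[["nll_star"]],
      seed = seed)
  }

  tr1 <- find_traj(both = FALSE, seed0 = cfg$seed)
  for (h in cfg$horizons) {
    times <- grid[grid <= h]
    res <- run_one(as_table(tr1, times), cfg$seed)
    add("i", "single trajectory, one mode", h, res, cfg$seed)
  }
  tr2 <- find_traj(both = TRUE, seed0 = cfg$seed + 1)
  for (h in cfg$horizons) {
    times <- grid[grid <= h]
    res <- run_one(as_table(tr2, times), cfg$seed)
    add("ii", "single trajectory, both modes, horizon", h, res, cfg$seed)
  }
  for (np in cfg$points_grid) {
    times <- seq(0, cfg$horizon, length.out = np + 1)[-1]
    tab <- as_table(tr2, times)
    res <- run_one(tab, cfg$seed)
    add("ii", "single trajectory, both modes, points", np, res, cfg$seed)
  }
  for (ct in cfg$counts) {
    tabs <- lapply(seq_len(ct), function(i) {
      tr <- ssa_trajectory(rates, cfg$n0, cfg$horizon,
                           seed = derive_seed(cfg$seed + 2, i))
      data.frame(trajectory_id = i, time = c(0, grid),
                 n = c(cfg$n0, sample_on_grid(tr, grid)))
    })
    res <- run_one(do.call(rbind, tabs), cfg$seed)
    add("iii", "multiple realisations", ct, res, cfg$seed)
  }
  do.call(rbind, rows)
}
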