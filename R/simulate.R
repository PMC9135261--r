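#' Stochastic simulation (SSA) of one trajectory
#'
#' Standard two-channel Gillespie algorithm for the birth-death chain:
#' exponential waiting times with total propensity `birth[n] + death[n]` and
#' channel chosen proportionally. The trajectory is piecewise constant between
#' events. If both propensities vanish the state is absorbing and the
#' trajectory terminates early (flagged, with a message).
#'
#' @param rates a [propensities()] rate table.
#' @param n0 initial state.
#' @param t_max simulation horizon, positive.
#' @param seed optional integer seed; with a fixed seed the event sequence is
#'   reproducible exactly.
#' @param max_events safety cap on the number of events.
#' @return An object of class `bd_trajectory`: `times` (strictly increasing,
#'   starting at 0), `states` (integers in `[0, N]`), `N`, `n0`, `t_max`,
#'   `seed` and an `absorbed` flag.
#' @examples
#' rt <- propensities(model_params(F = 0, J = 10, N = 100, beta = 1))
#' tr <- ssa_trajectory(rt, n0 = 50, t_max = 2, seed = 1)
#' range(tr$states)
#' @export
ssa_trajectory <- function(rates, n0, t_max, seed = NULL, max_events = 1e7) {
  stopifnot(inherits(rates, "bd_rates"), t_max > 0)
  check_state(n0, rates$N)
  if (!is.null(seed)) set.seed(seed)
  out <- ssa_core(rates$birth, rates$death, as.integer(n0), t_max,
                  as.integer(max_events))
  if (isTRUE(out$absorbed))
    message(sprintf("trajectory absorbed at state %d before t_max",
                    out$states[length(out$states)]))
  structure(list(times = out$times, states = as.integer(out$states),
                 N = rates$N, n0 = as.integer(n0), t_max = t_max,
                 seed = seed, absorbed = isTRUE(out$absorbed)),
            class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("SSA trajectory: %d events on [0, %g], n0 = %d, N = %d%s\n",
              length(x$times) - 1L, x$t_max, x$n0, x$N,
              if (x$absorbed) " (absorbed)" else ""))
  invisible(x)
}

#' Sample a trajectory on a time grid
#'
#' Left-continuous piecewise-constant lookup: the state at the most recent
#' event at or before each grid time (the natural reading of a cadlag counting
#' process at observation times).
#'
#' @param traj a [ssa_trajectory()] object.
#' @param grid observation times within `[0, t_max]`.
#' @return Integer vector of states, one per grid time.
#' @export
sample_on_grid <- function(traj, grid) {
  stopifnot(inherits(traj, "bd_trajectory"))
  if (any(grid < 0 | grid > traj$t_max))
    stop("grid times must lie within [0, t_max]")
  idx <- findInterval(grid, traj$times)
  traj$states[pmax(idx, 1L)]
}

derive_seed <- function(master, i) {
  # counter-based derivation: reproducible and independent of evaluation order
  as.integer((as.numeric(master) + as.numeric(i) * 9973) %% 2147483647)
}

#' Ensemble of SSA trajectories with per-time summaries
#'
#' Simulates `n_traj` independent trajectories (each with a seed derived from
#' the master seed by a counter scheme, so the ensemble is reproducible and
#' order-independent), samples them on a common grid and tabulates the
#' empirical distribution, mean and variance at every grid time.
#'
#' @param rates a [propensities()] rate table.
#' @param n0 initial state.
#' @param grid observation times (the horizon is `max(grid)`).
#' @param n_traj number of trajectories, `>= 1`.
#' @param seed master integer seed.
#' @return An object of class `bd_ensemble`: `grid`, `probs` (matrix
#'   `(N+1) x length(grid)`, columns normalised), `mean`, `var`, `states`
#'   (matrix `n_traj x length(grid)`), `n_traj`.
#' @export
ssa_ensemble <- function(rates, n0, grid, n_traj, seed = 1) {
  stopifnot(inherits(rates, "bd_rates"), n_traj >= 1)
  grid <- sort(grid)
  t_max <- max(grid)
  states <- matrix(0L, n_traj, length(grid))
  for (i in seq_len(n_traj)) {
    tr <- ssa_trajectory(rates, n0, t_max, seed = derive_seed(seed, i))
    states[i, ] <- sample_on_grid(tr, grid)
  }
  N <- rates$N
  probs <- apply(states, 2, function(s) tabulate(s + 1L, nbins = N + 1) / length(s))
  structure(list(grid = grid, probs = probs,
                 mean = colMeans(states),
                 var = apply(states, 2, stats::var),
                 states = states, n_traj = n_traj, N = N, seed = seed),
            class = "bd_ensemble")
}

#' @export
print.bd_ensemble <- function(x, ...) {
  cat(sprintf("SSA ensemble: %d trajectories on %d grid times in [%g, %g]\n",
              x$n_traj, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}
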