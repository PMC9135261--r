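#' Parameters of the mean-field binary decision model
#'
#' Container for the five scalars of the mean-field binary choice model plus
#' the population size. `F` is the exogenous field (zeitgeist) pushing every
#' agent equally towards one of the two choices; `J >= 0` is the conformity
#' (agent-to-agent interaction) strength; `alpha` in `[0, 1]` interpolates
#' between selfish (`0`) and fully altruistic (`1`) agents; `beta >= 0` is the
#' rationality (inverse-temperature analogue); `gamma > 0` sets the overall
#' decision time scale; `N >= 1` is the number of agents. The state of the
#' system is the count `n` of right-deciding agents, `0 <= n <= N`, with order
#' parameter `m(n) = (2n - N)/N`.
#'
#' @param F exogenous field, real.
#' @param J interaction strength, real, non-negative.
#' @param alpha altruism weight in `[0, 1]`.
#' @param beta rationality, non-negative.
#' @param gamma time-scale rate, positive.
#' @param N number of agents, integer `>= 1`.
#' @param include_self_interaction include the `2(1+alpha)J/N` self-interaction
#'   term in the gain (the change in `m(n)` caused by the flipping agent
#'   itself). On by default.
#' @return An object of class `bd_model`.
#' @examples
#' p <- model_params(F = 0.1, J = 5, N = 50)
#' influence(25, p)
#' @export
model_params <- function(F = 0, J = 1, alpha = 0, beta = 1, gamma = 1, N = 50,
                         include_self_interaction = TRUE) {
  stopifnot(is.numeric(F), length(F) == 1L, is.finite(F))
  if (J < 0) stop("J must be non-negative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (beta < 0) stop("beta must be non-negative")
  if (gamma <= 0) stop("gamma must be positive")
  if (N < 1 || N != round(N)) stop("N must be an integer >= 1")
  structure(
    list(F = F, J = J, alpha = alpha, beta = beta, gamma = gamma,
         N = as.integer(N),
         include_self_interaction = isTRUE(include_self_interaction)),
    class = "bd_model")
}

#' Parameters of the Kirman ant-recruitment model
#'
#' `epsilon` is the spontaneous (first-order) switching rate per agent and
#' `mu` the pairwise recruitment rate; at least one must be positive.
#'
#' @param epsilon spontaneous switching rate, non-negative.
#' @param mu recruitment rate, non-negative.
#' @param N number of agents, integer `>= 2`.
#' @return An object of class `bd_kirman`.
#' @export
kirman_params <- function(epsilon = 1, mu = 1, N = 50) {
  if (epsilon < 0 || mu < 0) stop("epsilon and mu must be non-negative")
  if (epsilon == 0 && mu == 0) stop("at least one of epsilon, mu must be positive")
  if (N < 2 || N != round(N)) stop("N must be an integer >= 2")
  structure(list(epsilon = epsilon, mu = mu, N = as.integer(N)),
            class = "bd_kirman")
}

#' @export
print.bd_model <- function(x, ...) {
  cat(sprintf(
    "Mean-field binary decision model: F = %g, J = %g, alpha = %g, beta = %g, gamma = %g, N = %d\n",
    x$F, x$J, x$alpha, x$beta, x$gamma, x$N))
  cat(sprintf("  self-interaction term: %s\n",
              if (x$include_self_interaction) "included" else "dropped"))
  invisible(x)
}

#' @export
print.bd_kirman <- function(x, ...) {
  cat(sprintf("Kirman recruitment model: epsilon = %g, mu = %g, N = %d\n",
              x$epsilon, x$mu, x$N))
  invisible(x)
}

#' Order parameter of a state
#'
#' Average opinion `m(n) = (2n - N)/N` for `n` right-deciding agents out of `N`.
#'
#' @param n state count (vectorised), `0 <= n <= N`.
#' @param N number of agents.
#' @return Numeric vector in `[-1, 1]`.
#' @export
order_parameter <- function(n, N) {
  check_state(n, N)
  (2 * n - N) / N
}

check_state <- function(n, N) {
  if (any(n < 0 | n > N | n != round(n)))
    stop("state count n must be an integer in [0, N]")
  invisible(n)
}

#' Shared influence on every agent
#'
#' The mean-field influence `I(n) = F + J m(n)` felt equally by all agents
#' when `n` of them decide right.
#'
#' @param n state count (vectorised).
#' @param params a [model_params()] object.
#' @return Numeric vector.
#' @export
influence <- function(n, params) {
  stopifnot(inherits(params, "bd_model"))
  check_state(n, params$N)
  params$F + params$J * order_parameter(n, params$N)
}

#' Gain (generalised utility change) for a single decision flip
#'
#' The gain `G = -2 S (F + J m(n)(1 + alpha)) + 2(1 + alpha) J / N`, where
#' `S = -1` for a left agent flipping right (`direction = "left_to_right"`)
#' and `S = +1` for a right agent flipping left. At `alpha = 0` this is the
#' selfish utility change; at `alpha = 1` it is the change in global utility.
#' The final self-interaction term is dropped when the model was built with
#' `include_self_interaction = FALSE`.
#'
#' @param direction `"left_to_right"` or `"right_to_left"`.
#' @param n state count before the flip (vectorised). A left-to-right flip
#'   requires `n < N`; a right-to-left flip requires `n > 0`.
#' @param params a [model_params()] object.
#' @return Numeric vector of gains.
#' @export
gain <- function(direction = c("left_to_right", "right_to_left"), n, params) {
  direction <- match.arg(direction)
  stopifnot(inherits(params, "bd_model"))
  check_state(n, params$N)
  S <- if (direction == "left_to_right") -1 else 1
  if (direction == "left_to_right" && any(n >= params$N))
    stop("no left-deciding agent to flip at n = N")
  if (direction == "right_to_left" && any(n <= 0))
    stop("no right-deciding agent to flip at n = 0")
  self <- if (params$include_self_interaction)
    2 * (1 + params$alpha) * params$J / params$N else 0
  -2 * S * (params$F + params$J * order_parameter(n, params$N) *
              (1 + params$alpha)) + self
}

#' Per-agent transition rate from a gain value
#'
#' Logit (Glauber) rule: `gamma / (1 + exp(-beta * g))`, which satisfies
#' detailed balance with the Boltzmann equilibrium. Arrhenius rule:
#' `gamma * exp(beta * g)`, where under this rule the caller supplies the
#' post-flip utility (not the utility change) as `g`.
#'
#' @param gain_value gain (logit) or post-flip utility (arrhenius), vectorised.
#' @param params a [model_params()] object supplying `beta` and `gamma`.
#' @param rule `"logit"` (default) or `"arrhenius"`.
#' @return Non-negative rates; the logit form saturates at `gamma` for large
#'   positive `beta * g` and at 0 for large negative values.
#' @export
transition_rate <- function(gain_value, params, rule = c("logit", "arrhenius")) {
  rule <- match.arg(rule)
  stopifnot(inherits(params, "bd_model"))
  if (rule == "logit") {
    params$gamma / (1 + exp(-params$beta * gain_value))
  } else {
    params$gamma * exp(params$beta * gain_value)
  }
}

#' Aggregate birth/death propensity table
#'
#' Maps the model onto a one-step birth-death chain over `n = 0, ..., N`.
#' For the decision model the aggregate propensities are
#' `birth[n] = (N - n) r(n)` and `death[n] = n l(n)`, with `r`, `l` the
#' per-agent left-to-right and right-to-left flip rates from the chosen rate
#' family. For Kirman's model, `birth[n] = (N - n) eps + mu (N - n) n/(N - 1)`
#' and `death[n] = n eps + mu (N - n) n/(N - 1)` (proportionality constant
#' absorbed into `epsilon` and `mu`). Boundary entries `birth[N]` and
#' `death[0]` are exactly zero.
#'
#' @param params a [model_params()] or [kirman_params()] object.
#' @param rule rate family for the decision model, `"logit"` or `"arrhenius"`;
#'   ignored for Kirman parameters.
#' @return An object of class `bd_rates`: list with `birth` and `death`
#'   (numeric vectors indexed by state `0:N`), `N`, the rate `family`, and a
#'   `params` snapshot.
#' @examples
#' rt <- propensities(model_params(F = 0.1, J = 5, N = 50))
#' rt$birth[51]  # birth at n = N is zero
#' @export
propensities <- function(params, rule = c("logit", "arrhenius")) {
  rule <- match.arg(rule)
  if (inherits(params, "bd_kirman")) {
    N <- params$N
    n <- 0:N
    rec <- params$mu * (N - n) * n / (N - 1)
    birth <- (N - n) * params$epsilon + rec
    death <- n * params$epsilon + rec
    family <- "kirman"
  } else if (inherits(params, "bd_model")) {
    N <- params$N
    n <- 0:N
    if (rule == "logit") {
      r <- transition_rate(gain("left_to_right", pmin(n, N - 1), params),
                           params, "logit")
      l <- transition_rate(gain("right_to_left", pmax(n, 1), params),
                           params, "logit")
    } else {
      # post-flip utility of the flipping agent: S_post * (F + (1+alpha) J m(n_post))
      u_up <- params$F + (1 + params$alpha) * params$J *
        order_parameter(pmin(n + 1, N), N)
      u_dn <- -(params$F + (1 + params$alpha) * params$J *
                  order_parameter(pmax(n - 1, 0), N))
      r <- transition_rate(u_up, params, "arrhenius")
      l <- transition_rate(u_dn, params, "arrhenius")
    }
    birth <- (N - n) * r
    death <- n * l
    family <- rule
  } else {
    stop("params must be a bd_model or bd_kirman object")
  }
  birth[N + 1] <- 0
  death[1] <- 0
  structure(list(birth = birth, death = death, N = N, family = family,
                 params = params),
            class = "bd_rates")
}

#' @export
print.bd_rates <- function(x, ...) {
  cat(sprintf("Birth-death rate table (%s family), N = %d states 0..%d\n",
              x$family, x$N, x$N))
  invisible(x)
}

#' Hamiltonian of the mean-field decision model
#'
#' `H(n) = N m(n) (F + (1/2)(alpha + 1) J m(n))`. The flip gain equals the
#' Hamiltonian increment, `H(n+1) - H(n) = gain("left_to_right", n)`, when the
#' self-interaction term is included, and the logit rates equilibrate to
#' `P_eq(n) proportional to C(N, n) exp(beta H(n))`.
#'
#' @param n state count (vectorised).
#' @param params a [model_params()] object.
#' @return Numeric vector.
#' @export
hamiltonian <- function(n, params) {
  stopifnot(inherits(params, "bd_model"))
  check_state(n, params$N)
  m <- order_parameter(n, params$N)
  params$N * m * (params$F + 0.5 * (params$alpha + 1) * params$J * m)
}

#' Critical rationality of the order-disorder transition
#'
#' For `F = 0` the steady state switches from monomodal to bimodal at
#' `beta_c = 1 / (J (1 + alpha))`.
#'
#' @param params a [model_params()] object with `J > 0`.
#' @return The critical rationality.
#' @export
critical_beta <- function(params) {
  stopifnot(inherits(params, "bd_model"))
  if (params$J <= 0) stop("no transition: J must be positive")
  1 / (params$J * (1 + params$alpha))
}

#' Mean-field fixed points of the order parameter
#'
#' Finds all real roots of the self-consistency equation
#' `m = tanh(beta (F + J (alpha + 1) m))` on `[-1, 1]` by a dense scan
#' followed by bisection refinement, and tags each root stable or unstable by
#' the slope of the map at the root (stable iff the derivative of
#' `tanh(beta(F + J(1+alpha) m))` is below 1). A smooth map of this form has
#' one or three roots.
#'
#' @param params a [model_params()] object.
#' @param resolution scan step on `[-1, 1]` (default `1e-4`).
#' @param tol bisection tolerance (default `1e-10`).
#' @return Data frame with columns `m` and `stable`.
#' @export
mean_field_fixed_points <- function(params, resolution = 1e-4, tol = 1e-10) {
  stopifnot(inherits(params, "bd_model"))
  Jp <- params$J * (1 + params$alpha)
  g <- function(m) tanh(params$beta * (params$F + Jp * m)) - m
  grid <- seq(-1, 1, by = resolution)
  v <- g(grid)
  roots <- numeric(0)
  exact <- which(v == 0)
  roots <- c(roots, grid[exact])
  sgn <- sign(v)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    r <- uniroot(g, lower = grid[i], upper = grid[i + 1], tol = tol)$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  # merge near-duplicates from scan/exact overlap
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 10 * resolution)]
  slope <- params$beta * Jp / cosh(params$beta * (params$F + Jp * roots))^2
  data.frame(m = roots, stable = slope < 1)
}
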