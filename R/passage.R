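#' Locate the metastable structure of a bimodal steady state
#'
#' Finds the two stable modes `n_minus < n_plus` (the two largest local maxima
#' of the steady-state distribution) and the unstable interior point `n_u`
#' (the argmin of `P_s` strictly between them, ties broken toward the
#' midpoint). A monomodal distribution raises a `bd_not_bistable` error.
#'
#' @param Ps a `bd_distribution`, typically from [steady_state()].
#' @return An object of class `bd_metastable` with integer states `n_minus`,
#'   `n_u`, `n_plus` and their order-parameter equivalents `m_minus`, `m_u`,
#'   `m_plus`.
#' @export
find_unstable_point <- function(Ps) {
  stopifnot(inherits(Ps, "bd_distribution"))
  p <- Ps$probs
  K <- length(p)
  left <- c(-Inf, p[-K])
  right <- c(p[-1], -Inf)
  peaks <- which(p >= left & p >= right & (p > left | p > right))
  if (length(peaks) < 2)
    stop(structure(class = c("bd_not_bistable", "error", "condition"),
                   list(message = "steady state is not bimodal", call = sys.call(-1))))
  ord <- peaks[order(p[peaks], decreasing = TRUE)]
  two <- sort(ord[1:2])
  nm <- two[1] - 1L
  np <- two[2] - 1L
  interior <- (nm + 2):np  # indices of states nm+1 .. np-1
  pm <- p[interior]
  cand <- interior[pm == min(pm)]
  mid <- (nm + np) / 2 + 1
  nu <- cand[which.min(abs(cand - mid))] - 1L
  N <- K - 1L
  structure(list(n_minus = nm, n_u = nu, n_plus = np,
                 m_minus = (2 * nm - N) / N, m_u = (2 * nu - N) / N,
                 m_plus = (2 * np - N) / N, N = N),
            class = "bd_metastable")
}

#' @export
print.bd_metastable <- function(x, ...) {
  cat(sprintf("Metastable structure: n_minus = %d, n_u = %d, n_plus = %d (m_u = %.3f)\n",
              x$n_minus, x$n_u, x$n_plus, x$m_u))
  invisible(x)
}

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

#' Exact mean first-passage times to the unstable point
#'
#' Closed-form double-sum/product expressions for the mean first-passage time
#' `tau_n` from every state `n` to the interior target `n_u`, with a
#' reflecting boundary at 0 for `n < n_u` and at `N` for `n > n_u`
#' (`tau_{n_u} = 0`). Evaluated in log-space so that barrier-dominated times
#' exponential in `N` do not overflow intermediate products. Equivalent to
#' solving the tridiagonal backward-equation system
#' `birth[n](tau_{n+1} - tau_n) + death[n](tau_{n-1} - tau_n) = -1` with the
#' two reflecting boundary conditions; [mfpt_solve()] does exactly that and is
#' the reference implementation the closed forms are validated against.
#'
#' @param rates a [propensities()] rate table.
#' @param n_u target state, strictly interior (`0 < n_u < N`).
#' @return Numeric vector `tau` of length `N + 1`, `tau[n_u + 1] = 0`.
#' @export
mfpt_exact <- function(rates, n_u) {
  stopifnot(inherits(rates, "bd_rates"))
  N <- rates$N
  if (n_u <= 0 || n_u >= N) stop("n_u must be strictly interior (0 < n_u < N)")
  tau <- numeric(N + 1)
  tau[(0:(n_u - 1)) + 1] <- mfpt_left_log(rates$birth, rates$death, n_u)
  refl <- list(birth = rev(rates$death), death = rev(rates$birth))
  tau_r <- mfpt_left_log(refl$birth, refl$death, N - n_u)
  tau[((n_u + 1):N) + 1] <- rev(tau_r)
  tau
}

# MFPT from states 0..target-1 to `target`, reflecting at 0, in log-space.
# la[j] = log a_j = log birth at state j-1; lb[i] = log b_i = log death at
# state i+1. -eta_i = sum_{j<=i} exp(-la_j + cum_{i-1} - cum_{j-1}) with
# cum_j = sum_{k<=j} (lb_{k-1} - la_{k+1}).
mfpt_left_log <- function(birth, death, target) {
  la <- log(birth)            # la[j] = log a_j, j = 1..target (R index j)
  lb <- log(death)            # death[s+1] = b_{s-1}; b_i = death[i+2]
  cum <- c(0, cumsum(lb[(0:(target - 2)) + 2] - la[(2:target)]))
  # cum[j+1] = cum_j for j = 0..target-1
  inner <- -la[1:target] - cum  # element j: -log a_j - cum_{j-1}
  lse <- numeric(target)       # running logsumexp over j <= i
  acc <- -Inf
  for (i in 1:target) {
    acc <- logsumexp(c(acc, inner[i]))
    lse[i] <- acc
  }
  log_negeta <- cum + lse      # log(-eta_i), i = 1..target
  # tau_n = sum_{i = n+1}^{target} (-eta_i), n = 0..target-1
  vapply(0:(target - 1), function(n) exp(logsumexp(log_negeta[(n + 1):target])),
         numeric(1))
}

#' Mean first-passage times via the linear backward system
#'
#' Solves the tridiagonal system
#' `birth[n] tau_{n+1} + death[n] tau_{n-1} - (birth[n] + death[n]) tau_n = -1`
#' on each side of the absorbing target `n_u` (reflecting at 0 and `N`).
#' Reference implementation for [mfpt_exact()].
#'
#' @inheritParams mfpt_exact
#' @return Numeric vector `tau` of length `N + 1`.
#' @export
mfpt_solve <- function(rates, n_u) {
  stopifnot(inherits(rates, "bd_rates"))
  N <- rates$N
  if (n_u <= 0 || n_u >= N) stop("n_u must be strictly interior (0 < n_u < N)")
  tau <- numeric(N + 1)
  solve_side <- function(states) {
    k <- length(states)
    M <- matrix(0, k, k)
    for (r in seq_len(k)) {
      s <- states[r]
      M[r, r] <- -(rates$birth[s + 1] + rates$death[s + 1])
      if (r > 1) M[r, r - 1] <- rates$death[s + 1]
      if (r < k) M[r, r + 1] <- rates$birth[s + 1]
    }
    solve(M, rep(-1, k))
  }
  tau[(0:(n_u - 1)) + 1] <- solve_side(0:(n_u - 1))
  tau[((n_u + 1):N) + 1] <- solve_side((n_u + 1):N)
  tau
}

#' Splitting probability from the unstable point
#'
#' The probability `phi_R` that a chain started at `n_u` reaches the right
#' mode `n_plus` before the left mode `n_minus`. Computed from the discrete
#' harmonic function `h` with `h(n_minus) = 0`, `h(n_plus) = 1` and
#' `birth[n](h(n+1) - h(n)) = death[n](h(n) - h(n-1))`, via the standard
#' product-ratio summation in log-space. The absorbing boundaries are the two
#' steady-state modes (coalescing on a technology means reaching its mode),
#' not the hard walls 0 and `N`.
#'
#' @param rates a [propensities()] rate table.
#' @param struct a [find_unstable_point()] structure.
#' @return `phi_R` in `[0, 1]`.
#' @export
splitting_probability <- function(rates, struct) {
  stopifnot(inherits(rates, "bd_rates"), inherits(struct, "bd_metastable"))
  nm <- struct$n_minus
  np <- struct$n_plus
  nu <- struct$n_u
  # h(n_u) = sum_{k=nm}^{nu-1} w_k / sum_{k=nm}^{np-1} w_k,
  # w_k = prod_{j=nm+1}^{k} death[j]/birth[j]
  s <- (nm + 1):(np - 1)
  lr <- c(0, cumsum(log(rates$death[s + 1]) - log(rates$birth[s + 1])))
  num <- logsumexp(lr[1:(nu - nm)])
  den <- logsumexp(lr)
  exp(num - den)
}

#' Mode escape times from conditional steady-state weights
#'
#' Weights the exact first-passage times by the steady-state mass conditioned
#' on each side of `n_u`: `rho_l(n) = P_s(n) / sum_{n < n_u} P_s` and
#' similarly `rho_r`, giving `tau_lr = sum_{n < n_u} rho_l(n) tau_n` (mean
#' time to escape the left mode) and `tau_rl` for the right mode.
#'
#' @param rates a [propensities()] rate table.
#' @param Ps steady-state `bd_distribution`.
#' @param struct a [find_unstable_point()] structure.
#' @param tau mean first-passage times from [mfpt_exact()] (computed if `NULL`).
#' @return List with `tau_lr`, `tau_rl`, and the weight vectors `rho_l`
#'   (over `n = 0..n_u-1`) and `rho_r` (over `n = n_u+1..N`).
#' @export
mode_escape_times <- function(rates, Ps, struct, tau = NULL) {
  stopifnot(inherits(Ps, "bd_distribution"), inherits(struct, "bd_metastable"))
  if (is.null(tau)) tau <- mfpt_exact(rates, struct$n_u)
  nu <- struct$n_u
  N <- struct$N
  il <- 1:nu                 # states 0..n_u-1
  ir <- (nu + 2):(N + 1)     # states n_u+1..N
  rho_l <- Ps$probs[il] / sum(Ps$probs[il])
  rho_r <- Ps$probs[ir] / sum(Ps$probs[ir])
  list(tau_lr = sum(rho_l * tau[il]), tau_rl = sum(rho_r * tau[ir]),
       rho_l = rho_l, rho_r = rho_r)
}

#' Two-state approximation of the relaxation rate
#'
#' `lambda_2 = phi_R / tau_lr + (1 - phi_R) / tau_rl`: the escape rates from
#' each mode, each weighted by the probability of committing to the opposite
#' mode on reaching `n_u`. Slightly underestimates the true relaxation rate
#' magnitude because the initial relaxation into the metastable state (of
#' order `1/|lambda_3|`) is not accounted for.
#'
#' @param phi_R splitting probability.
#' @param tau_lr,tau_rl mode escape times.
#' @return The approximate relaxation rate `lambda_2 > 0` (its reciprocal is
#'   the relaxation time).
#' @export
relaxation_rate <- function(phi_R, tau_lr, tau_rl) {
  stopifnot(tau_lr > 0, tau_rl > 0, phi_R >= 0, phi_R <= 1)
  phi_R / tau_lr + (1 - phi_R) / tau_rl
}

#' Two-state reduction of the metastable dynamics
#'
#' Closed-form solution of the linear two-state exchange
#' `d pi_L/dt = -phi_R pi_L / tau_lr + (1 - phi_R) pi_R / tau_rl` with
#' `pi_L + pi_R = 1`: `pi_L(t) = pi_L^s + (pi_L(0) - pi_L^s) exp(-lambda_2 t)`
#' and stationary ratio `pi_L^s / pi_R^s = tau_lr (1 - phi_R) / (tau_rl phi_R)`.
#'
#' @param phi_R splitting probability.
#' @param tau_lr,tau_rl mode escape times.
#' @param piL0 initial left-mode mass.
#' @return List with functions `pi_L(t)`, `pi_R(t)`, the rate `lambda2`,
#'   stationary masses `piL_s`, `piR_s` and their `stationary_ratio`.
#' @export
two_state_reduction <- function(phi_R, tau_lr, tau_rl, piL0) {
  stopifnot(piL0 >= 0, piL0 <= 1)
  lambda2 <- relaxation_rate(phi_R, tau_lr, tau_rl)
  piL_s <- ((1 - phi_R) / tau_rl) / lambda2
  pi_L <- function(t) piL_s + (piL0 - piL_s) * exp(-lambda2 * t)
  list(pi_L = pi_L, pi_R = function(t) 1 - pi_L(t),
       lambda2 = lambda2, piL_s = piL_s, piR_s = 1 - piL_s,
       stationary_ratio = tau_lr * (1 - phi_R) / (tau_rl * phi_R))
}

#' Closed-form distribution in the metastable regime
#'
#' For times beyond the fast initial relaxation (`t >> 1/|lambda_3|`) the
#' distribution is approximately `P_s + exp(-lambda_2 t) Phi_2`, where
#' `Phi_2(n) = (pi_L(0) - pi_L^s) [rho_l(n) 1{n < n_u} - rho_r(n) 1{n > n_u}]`
#' is a signed vector summing to zero. Needs no eigenvalue computation beyond
#' the two-state `lambda_2`.
#'
#' @param Ps steady-state `bd_distribution`.
#' @param struct a [find_unstable_point()] structure.
#' @param lambda2 relaxation rate (e.g. from [relaxation_rate()]).
#' @param piL0 initial left-mode mass.
#' @param t time in the metastable regime.
#' @return A `bd_distribution`; errors if `t` is too small for the
#'   approximation to stay non-negative (use the full spectral solution there).
#' @export
metastable_distribution <- function(Ps, struct, lambda2, piL0, t) {
  stopifnot(inherits(Ps, "bd_distribution"), inherits(struct, "bd_metastable"))
  nu <- struct$n_u
  N <- struct$N
  piL_s <- sum(Ps$probs[1:nu])
  phi2 <- numeric(N + 1)
  rho_l <- Ps$probs[1:nu] / sum(Ps$probs[1:nu])
  rho_r <- Ps$probs[(nu + 2):(N + 1)] / sum(Ps$probs[(nu + 2):(N + 1)])
  phi2[1:nu] <- (piL0 - piL_s) * rho_l
  phi2[(nu + 2):(N + 1)] <- -(piL0 - piL_s) * rho_r
  p <- Ps$probs + exp(-lambda2 * t) * phi2
  if (min(p) < -1e-12)
    stop("metastable approximation yields negative probabilities; t is below its validity threshold - use transient_distribution()")
  p[p < 0] <- 0
  finalise_distribution(p / sum(p), list(N = N), "metastable distribution")
}

#' Initial mode mass for the metastable closed form
#'
#' The default policy for the `piL0` argument of [metastable_distribution()]:
#' a chain started exactly at the unstable point commits left with probability
#' `1 - phi_R`; started anywhere else, the left-mode mass is read off the full
#' transient solution at `t = 10 / |Re lambda_3|`, i.e. after the fast
#' intra-mode relaxation has finished but before any appreciable inter-mode
#' exchange.
#'
#' @param rates a [propensities()] rate table.
#' @param struct a [find_unstable_point()] structure.
#' @param n0 initial state.
#' @return The initial left-mode mass `pi_L(0)`.
#' @export
initial_left_mass <- function(rates, struct, n0) {
  stopifnot(inherits(struct, "bd_metastable"))
  check_state(n0, struct$N)
  if (n0 == struct$n_u)
    return(1 - splitting_probability(rates, struct))
  sp <- operator_spectrum(rates)
  t3 <- 10 / abs(Re(sp$lambda3))
  d <- suppressMessages(transient_distribution(rates, n0, t3))
  sum(d$probs[1:struct$n_u])
}

#' Continuum (Fokker-Planck) asymptotic exponents of the escape times
#'
#' In the diffusion approximation with strong rationality the escape times
#' grow exponentially with the number of agents:
#' `tau_lr ~ exp(N (1 - F / (J(1+alpha))))` and
#' `tau_rl ~ exp(N (1 + F / (J(1+alpha))))`. Only the exponents are returned
#' (the prefactors require the full continuum calculation).
#'
#' @param params a [model_params()] object.
#' @return Named vector `c(exponent_lr, exponent_rl)`.
#' @export
mfpt_asymptotic_exponent <- function(params) {
  stopifnot(inherits(params, "bd_model"))
  ratio <- params$F / (params$J * (1 + params$alpha))
  c(exponent_lr = params$N * (1 - ratio), exponent_rl = params$N * (1 + ratio))
}

#' Full metastability report for a bistable chain
#'
#' Convenience pipeline: steady state, unstable point, exact first-passage
#' times, splitting probability, mode escape times, two-state relaxation rate
#' and stationary mode masses.
#'
#' @param rates a [propensities()] rate table with a bimodal steady state.
#' @return An object of class `bd_passage` collecting all quantities.
#' @examples
#' rt <- propensities(model_params(F = 0.025, J = 1.5, N = 50))
#' pr <- passage_analysis(rt)
#' 1 / pr$lambda2_approx
#' @export
passage_analysis <- function(rates) {
  Ps <- steady_state(rates)
  struct <- find_unstable_point(Ps)
  tau <- mfpt_exact(rates, struct$n_u)
  esc <- mode_escape_times(rates, Ps, struct, tau)
  phi_R <- splitting_probability(rates, struct)
  lambda2 <- relaxation_rate(phi_R, esc$tau_lr, esc$tau_rl)
  two <- two_state_reduction(phi_R, esc$tau_lr, esc$tau_rl, piL0 = 1 - phi_R)
  structure(list(steady_state = Ps, structure = struct, tau = tau,
                 tau_lr = esc$tau_lr, tau_rl = esc$tau_rl,
                 rho_l = esc$rho_l, rho_r = esc$rho_r, phi_R = phi_R,
                 lambda2_approx = lambda2,
                 relaxation_time_approx = 1 / lambda2,
                 pi_L_s = two$piL_s, pi_R_s = two$piR_s),
            class = "bd_passage")
}

#' @export
print.bd_passage <- function(x, ...) {
  s <- x$structure
  cat("Metastability analysis\n")
  cat(sprintf("  modes: n_minus = %d, n_u = %d, n_plus = %d\n",
              s$n_minus, s$n_u, s$n_plus))
  cat(sprintf("  phi_R = %.6f\n", x$phi_R))
  cat(sprintf("  tau_lr = %.6g, tau_rl = %.6g\n", x$tau_lr, x$tau_rl))
  cat(sprintf("  lambda2 (two-state approx) = %.6g, 1/lambda2 = %.6g\n",
              x$lambda2_approx, x$relaxation_time_approx))
  cat(sprintf("  stationary masses: pi_L = %.4f, pi_R = %.4f\n",
              x$pi_L_s, x$pi_R_s))
  invisible(x)
}
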