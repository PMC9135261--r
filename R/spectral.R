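#' Build the master operator of a birth-death chain
#'
#' The generator `A` of the one-step chain: an `(N+1) x (N+1)` tridiagonal
#' matrix with sub-diagonal `birth[0..N-1]`, super-diagonal `death[1..N]` and
#' diagonal `-(birth + death)`, acting on probability column vectors via
#' `dP/dt = A P`. Every column sums to zero (probability conservation).
#'
#' @param rates a [propensities()] rate table.
#' @return A dense numeric matrix of dimension `N + 1`.
#' @export
build_operator <- function(rates) {
  stopifnot(inherits(rates, "bd_rates"))
  N <- rates$N
  A <- matrix(0, N + 1, N + 1)
  diag(A) <- -(rates$birth + rates$death)
  A[cbind(2:(N + 1), 1:N)] <- rates$birth[1:N]
  A[cbind(1:N, 2:(N + 1))] <- rates$death[2:(N + 1)]
  A
}

#' Eigenvalues of the master operator
#'
#' All `N + 1` eigenvalues sorted by descending real part. By
#' Perron-Frobenius the largest is exactly zero for an irreducible chain; the
#' computed `lambda_1` is snapped to 0 when it lies within
#' `1e-8 * ||A||_inf` of it. Finite-precision eigensolvers may return complex
#' conjugate pairs (a pseudospectrum) for these highly non-normal matrices;
#' the pairs are retained and later summed in complex arithmetic.
#' `1/|Re(lambda_2)|` is the relaxation time of the chain.
#'
#' @param op a master operator matrix from [build_operator()], or a
#'   [propensities()] rate table.
#' @param degeneracy_tol relative gap (in units of `||A||_inf`) below which
#'   two eigenvalues are flagged as numerically degenerate, in which case
#'   transient evaluation falls back to the matrix exponential.
#' @return An object of class `bd_spectrum`: complex `values` (sorted),
#'   `lambda1/lambda2/lambda3`, `relaxation_time`, logical `degenerate`,
#'   and the operator norm `anorm`.
#' @examples
#' sp <- operator_spectrum(propensities(model_params(F = 0.025, J = 1.5, N = 50)))
#' sp$relaxation_time
#' @export
operator_spectrum <- function(op, degeneracy_tol = 1e-8) {
  if (inherits(op, "bd_rates")) op <- build_operator(op)
  stopifnot(is.matrix(op), nrow(op) == ncol(op))
  anorm <- max(abs(op)) * nrow(op)
  lam <- eigen(op, only.values = TRUE)$values
  lam <- as.complex(lam)
  lam <- lam[order(-Re(lam), abs(Im(lam)))]
  if (abs(lam[1]) > 1e-8 * max(anorm, 1))
    warning("largest eigenvalue deviates from 0 by more than the tolerance")
  lam[1] <- 0 + 0i
  gaps <- abs(outer(lam, lam, "-"))
  diag(gaps) <- Inf
  degenerate <- min(gaps) < degeneracy_tol * max(anorm, 1)
  n <- length(lam)
  structure(
    list(values = lam,
         lambda1 = lam[1],
         lambda2 = if (n >= 2) lam[2] else NA_complex_,
         lambda3 = if (n >= 3) lam[3] else NA_complex_,
         relaxation_time = if (n >= 2) 1 / abs(Re(lam[2])) else NA_real_,
         degenerate = degenerate,
         anorm = anorm),
    class = "bd_spectrum")
}

#' @export
print.bd_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum of %d x %d master operator\n",
              length(x$values), length(x$values)))
  cat(sprintf("  lambda2 = %s, relaxation time 1/|Re lambda2| = %.6g\n",
              format(x$lambda2, digits = 6), x$relaxation_time))
  if (x$degenerate) cat("  note: numerically degenerate eigenvalue pair detected\n")
  invisible(x)
}

# --- resolvent-polynomial machinery -----------------------------------------
#
# With a_i = birth[i-1] and b_i = death[i+1] (states 0..N), the transient
# solution from a point initial condition is a sum of residues of the
# resolvent of A. The residue weights are products of characteristic
# polynomials of leading (p) and trailing (q) principal minors of (yI - A),
# evaluated at each eigenvalue, divided by prod_{j != i}(lambda_i - lambda_j).
# Minors span hundreds of orders of magnitude for moderate N, so the
# recursions are run on (complex mantissa, power-of-two exponent) pairs.

# a_i, i >= 1 (a_{N+1} = 0); b_i, 0 <= i <= N-1; both 0 outside their range.
aval <- function(rates, i) ifelse(i >= 1 & i <= rates$N + 1, rates$birth[pmax(i, 1)], 0)
bval <- function(rates, i) ifelse(i >= 0 & i <= rates$N - 1, rates$death[pmax(i + 2, 1)], 0)

rescale_step <- function(mant, expo) {
  s <- Mod(mant)
  adj <- ifelse(s > 0 & (s > 2^200 | s < 2^-200), floor(log2(s)), 0)
  list(mant = mant * 2^(-adj), expo = expo + adj)
}

# p_k = leading principal minor of (yI - A) of size k-1, evaluated at each
# eigenvalue; rows k = 1..N+2, columns = eigenvalues.
poly_forward <- function(rates, lam) {
  N <- rates$N
  K <- length(lam)
  mant <- matrix(0 + 0i, N + 2, K)
  expo <- matrix(0, N + 2, K)
  mant[1, ] <- 1 + 0i
  mant[2, ] <- lam + aval(rates, 1)
  for (i in 3:(N + 2)) {
    c1 <- lam + aval(rates, i - 1) + bval(rates, i - 3)
    c2 <- bval(rates, i - 3) * aval(rates, i - 2)
    eb <- pmax(expo[i - 1, ], expo[i - 2, ])
    m <- c1 * mant[i - 1, ] * 2^(expo[i - 1, ] - eb) -
      c2 * mant[i - 2, ] * 2^(expo[i - 2, ] - eb)
    r <- rescale_step(m, eb)
    mant[i, ] <- r$mant
    expo[i, ] <- r$expo
  }
  list(mant = mant, expo = expo)
}

# q_k = trailing principal minor of (yI - A) over matrix rows k..N+1.
poly_backward <- function(rates, lam) {
  N <- rates$N
  K <- length(lam)
  mant <- matrix(0 + 0i, N + 2, K)
  expo <- matrix(0, N + 2, K)
  mant[N + 2, ] <- 1 + 0i
  mant[N + 1, ] <- lam + bval(rates, N - 1)
  if (N >= 1) {
    for (i in N:1) {
      c1 <- lam + aval(rates, i) + bval(rates, i - 2)
      c2 <- bval(rates, i - 1) * aval(rates, i)
      eb <- pmax(expo[i + 1, ], expo[i + 2, ])
      m <- c1 * mant[i + 1, ] * 2^(expo[i + 1, ] - eb) -
        c2 * mant[i + 2, ] * 2^(expo[i + 2, ] - eb)
      r <- rescale_step(m, eb)
      mant[i, ] <- r$mant
      expo[i, ] <- r$expo
    }
  }
  list(mant = mant, expo = expo)
}

# Cache of everything that depends on the rate table but not on n0 or t.
spectral_cache <- function(rates, degeneracy_tol = 1e-8) {
  spec <- operator_spectrum(build_operator(rates), degeneracy_tol)
  lam <- spec$values
  K <- length(lam)
  # complex log of prod_{j != i}(lambda_i - lambda_j)
  logden <- vapply(seq_len(K), function(i) {
    d <- lam[i] - lam[-i]
    sum(log(d))
  }, complex(1))
  list(rates = rates, spec = spec, lam = lam,
       p = poly_forward(rates, lam), q = poly_backward(rates, lam),
       logden = logden,
       logb = log(rates$death),   # index s+1 = log death at state s
       loga = log(rates$birth))   # index s+1 = log birth at state s
}

# Complex residue weight matrix C with P(n, t | n0) = Re(C %*% exp(lam t)).
# Returns NULL if the weights are not representable in double precision
# (severe pseudospectrum); callers then fall back to the matrix exponential.
transient_weights <- function(cache, n0) {
  rates <- cache$rates
  N <- rates$N
  K <- N + 1
  ln2 <- log(2)
  # log prefactors: products of deaths (n < n0) or births (n > n0)
  logpref <- numeric(N + 1)
  if (n0 >= 1) {
    # state n < n0: b_n ... b_{n0-1} = death[n+1..n0]
    cs <- rev(cumsum(rev(cache$logb[(1:n0) + 1])))
    logpref[1:n0] <- cs
  }
  if (n0 <= N - 1) {
    # state n > n0: a_{n0+1} ... a_n = birth[n0..n-1]
    cs <- cumsum(cache$loga[((n0 + 1):N - 1) + 1])
    logpref[(n0 + 2):(N + 1)] <- cs
  }
  # row n+1 uses p_{n+1} (n <= n0) or p_{n0+1} (n > n0), and q_{n0+2}
  # (n <= n0) or q_{n+2} (n > n0).
  pm <- cache$p$mant
  pe <- cache$p$expo
  qm <- cache$q$mant
  qe <- cache$q$expo
  C <- matrix(0 + 0i, N + 1, K)
  for (n in 0:N) {
    if (n <= n0) {
      mant <- pm[n + 1, ] * qm[n0 + 2, ]
      expo <- pe[n + 1, ] + qe[n0 + 2, ]
    } else {
      mant <- pm[n0 + 1, ] * qm[n + 2, ]
      expo <- pe[n0 + 1, ] + qe[n + 2, ]
    }
    lg <- log(mant) + expo * ln2 + logpref[n + 1] - cache$logden
    C[n + 1, ] <- exp(lg)
  }
  if (!all(is.finite(Re(C)) & is.finite(Im(C)))) return(NULL)
  C
}

expm_probs <- function(rates, n0, t) {
  # propagate along the sorted grid, caching the propagator for repeated
  # step sizes (uniform grids then cost a single expm)
  A <- build_operator(rates)
  ord <- order(t)
  ts <- t[ord]
  P <- matrix(0, rates$N + 1, length(t))
  v <- numeric(rates$N + 1)
  v[n0 + 1] <- 1
  prev <- 0
  steps <- list()
  for (k in seq_along(ts)) {
    dt <- ts[k] - prev
    if (dt > 0) {
      key <- sprintf("%.15g", dt)
      if (is.null(steps[[key]]))
        steps[[key]] <- as.matrix(Matrix::expm(Matrix::Matrix(A * dt)))
      v <- as.numeric(steps[[key]] %*% v)
    }
    P[, ord[k]] <- v
    prev <- ts[k]
  }
  P
}

finalise_distribution <- function(probs, rates, what = "distribution") {
  if (min(probs) < -1e-9)
    stop(sprintf("%s has entries below -1e-9; spectral evaluation unreliable", what))
  probs[probs < 0] <- 0
  s <- sum(probs)
  if (abs(s - 1) > 1e-6)
    stop(sprintf("%s fails to normalise (sum = %.8g)", what, s))
  probs <- as.numeric(probs) / s
  structure(list(n = 0:rates$N,
                 m = (2 * (0:rates$N) - rates$N) / rates$N,
                 probs = probs),
            class = "bd_distribution")
}

#' @export
print.bd_distribution <- function(x, ...) {
  cat(sprintf("Distribution over n = 0..%d (mean m = %.4f)\n",
              length(x$probs) - 1, sum(x$m * x$probs)))
  invisible(x)
}

#' @export
as.data.frame.bd_distribution <- function(x, ...) {
  data.frame(n = x$n, m = x$m, probability = x$probs)
}

#' Exact transient distribution of the chain
#'
#' Evaluates the spectral (resolvent residue) solution of the master equation
#' from a point initial condition `n0`: a three-branch formula whose terms are
#' products of characteristic polynomials of principal minors of the
#' generator evaluated at each eigenvalue, times `exp(lambda_i t)`, divided by
#' `prod_{j != i}(lambda_i - lambda_j)`. Terms are combined in sign/log-scaled
#' arithmetic because the polynomial values span hundreds of orders of
#' magnitude; complex-conjugate eigenvalue pairs from the pseudospectrum are
#' summed in complex arithmetic and the real part returned. If the spectrum
#' is numerically degenerate, the residue weights overflow, a residual
#' imaginary part above `1e-8` survives, or normalisation fails, the function
#' falls back to a matrix-exponential evaluation (with a message).
#'
#' @param rates a [propensities()] rate table with strictly positive interior
#'   rates (irreducible chain).
#' @param n0 initial state, `0 <= n0 <= N`.
#' @param t time, a non-negative scalar.
#' @param degeneracy_tol see [operator_spectrum()].
#' @return A `bd_distribution`: probabilities over `n = 0..N`, normalised.
#' @examples
#' rt <- propensities(model_params(F = 0.1, J = 5, N = 50))
#' d <- transient_distribution(rt, n0 = 25, t = 10)
#' sum(d$probs)
#' @export
transient_distribution <- function(rates, n0, t, degeneracy_tol = 1e-8) {
  stopifnot(inherits(rates, "bd_rates"), length(t) == 1L, t >= 0)
  check_state(n0, rates$N)
  if (t == 0) {
    probs <- numeric(rates$N + 1)
    probs[n0 + 1] <- 1
    return(finalise_distribution(probs, rates))
  }
  cache <- spectral_cache(rates, degeneracy_tol)
  probs <- transient_probs_cached(cache, n0, t)[, 1]
  finalise_distribution(probs, rates, "transient distribution")
}

# Core evaluation shared by the public solver and the likelihood. Returns a
# matrix of probabilities, one column per time, clipped and renormalised.
transient_probs_cached <- function(cache, n0, tvec) {
  rates <- cache$rates
  fallback <- function() {
    message("spectral evaluation unreliable; falling back to matrix exponential")
    P <- expm_probs(rates, n0, tvec)
    P[P < 0] <- 0
    sweep(P, 2, colSums(P), "/")
  }
  if (cache$spec$degenerate) return(fallback())
  C <- transient_weights(cache, n0)
  if (is.null(C)) return(fallback())
  E <- exp(outer(cache$lam, tvec))
  Z <- C %*% E
  if (max(abs(Im(Z))) > 1e-8) return(fallback())
  P <- Re(Z)
  if (min(P) < -1e-9) return(fallback())
  P <- clip_columns(P)
  if (is.null(P)) return(fallback())
  P
}

clip_columns <- function(P) {
  P <- matrix(P, nrow = nrow(as.matrix(P)))
  P[P < 0 & P > -1e-9] <- 0
  s <- colSums(P)
  if (any(abs(s - 1) > 1e-6) || any(P < 0)) return(NULL)
  sweep(P, 2, s, "/")
}

#' Transient distribution from a distributed initial condition
#'
#' Mixture over point initial conditions: `sum_{n0} Q(n0) P(n, t | n0, 0)`.
#'
#' @param rates a [propensities()] rate table.
#' @param Q initial distribution: a `bd_distribution` or a numeric vector of
#'   length `N + 1` summing to 1.
#' @param t time, non-negative scalar.
#' @param degeneracy_tol see [operator_spectrum()].
#' @return A `bd_distribution` at time `t`.
#' @export
transient_from_mixture <- function(rates, Q, t, degeneracy_tol = 1e-8) {
  stopifnot(inherits(rates, "bd_rates"))
  q <- if (inherits(Q, "bd_distribution")) Q$probs else as.numeric(Q)
  if (length(q) != rates$N + 1) stop("Q must have N + 1 entries")
  if (any(q < 0) || abs(sum(q) - 1) > 1e-8) stop("Q must be a normalised distribution")
  if (t == 0) return(finalise_distribution(q, rates))
  cache <- spectral_cache(rates, degeneracy_tol)
  probs <- numeric(rates$N + 1)
  for (n0 in which(q > 0) - 1)
    probs <- probs + q[n0 + 1] * transient_probs_cached(cache, n0, t)[, 1]
  finalise_distribution(probs, rates, "mixture distribution")
}

#' Kirchhoff steady state of the chain
#'
#' The stationary distribution of a one-step birth-death chain:
#' `P_s(n)` proportional to `prod_{i=1..n} a_i * prod_{i=n..N-1} b_i` with
#' `a_i = birth[i-1]`, `b_i = death[i+1]`, computed in log-space and
#' normalised. Independent of the initial condition. For the logit family this
#' equals the Boltzmann form `C(N, n) exp(beta H(n)) / Z`.
#'
#' @param rates a [propensities()] rate table (irreducible chain).
#' @return A `bd_distribution`.
#' @examples
#' ps <- steady_state(propensities(model_params(F = 0, J = 10, beta = 1, N = 100)))
#' ps$probs[c(1, 101)]  # two symmetric boundary modes
#' @export
steady_state <- function(rates) {
  stopifnot(inherits(rates, "bd_rates"))
  N <- rates$N
  lw <- numeric(N + 1)
  for (n in 1:N)
    lw[n + 1] <- lw[n] + log(rates$birth[n]) - log(rates$death[n + 1])
  w <- exp(lw - max(lw))
  finalise_distribution(w / sum(w), rates, "steady state")
}
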