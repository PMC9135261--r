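# Shared fixtures: the published parameter sets and small random chains.

params_fig1 <- function() model_params(F = 0, J = 10, alpha = 0, beta = 1,
                                       gamma = 1, N = 100)
params_fig2 <- function() model_params(F = 0.1, J = 5, alpha = 0, beta = 1,
                                       gamma = 1, N = 50)
params_fig3 <- function() model_params(F = 0.025, J = 1.5, alpha = 0, beta = 1,
                                       gamma = 1, N = 50)

random_params <- function() {
  model_params(F = runif(1, -0.5, 0.5), J = runif(1, 0.1, 3),
               alpha = runif(1), beta = runif(1, 0.1, 2),
               gamma = runif(1, 0.5, 2), N = sample(10:40, 1))
}

# A raw rate table with strictly positive interior rates, not tied to any
# decision model (exercises the solver on arbitrary irreducible chains).
random_rate_table <- function(N) {
  birth <- c(runif(N, 0.2, 2), 0)
  death <- c(0, runif(N, 0.2, 2))
  structure(list(birth = birth, death = death, N = N, family = "raw",
                 params = NULL), class = "bd_rates")
}

# Independent matrix-exponential oracle for the transient distribution.
oracle_expm <- function(rates, n0, t) {
  A <- build_operator(rates)
  d <- numeric(rates$N + 1)
  d[n0 + 1] <- 1
  as.numeric(Matrix::expm(Matrix::Matrix(A * t)) %*% d)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
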