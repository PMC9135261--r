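test_that("influence is the field plus conformity times the order parameter", {
  p <- params_fig2()
  expect_equal(influence(25, p), 0.1)                      # m = 0
  expect_equal(influence(50, p), 5.1)                      # m = 1
  expect_equal(influence(0, model_params(F = 0, J = 10, N = 100)), -10)
  expect_error(influence(51, p), "in \\[0, N\\]")
})

test_that("gain reduces to the selfish utility change and is antisymmetric", {
  p <- model_params(F = 0.1, J = 5, alpha = 0, N = 50)
  # alpha = 0: G = -2 S I(n) + 2J/N
  n <- 0:49
  expect_equal(gain("left_to_right", n, p),
               2 * influence(n, p) + 2 * p$J / p$N)
  expect_equal(gain("left_to_right", 25, p), 0.4)
  for (i in 1:5) {
    set.seed(i)
    q <- random_params()
    n <- 0:(q$N - 1)
    expect_equal(gain("left_to_right", n, q),
                 -gain("right_to_left", n + 1, q))
  }
  expect_error(gain("left_to_right", p$N, p), "no left-deciding")
  expect_error(gain("right_to_left", 0, p), "no right-deciding")
})

test_that("the gain equals the Hamiltonian increment across the state space", {
  for (i in 1:5) {
    set.seed(100 + i)
    q <- random_params()
    n <- 0:(q$N - 1)
    expect_equal(hamiltonian(n + 1, q) - hamiltonian(n, q),
                 gain("left_to_right", n, q), tolerance = 1e-12)
  }
  p <- params_fig1()
  expect_equal(hamiltonian(50, p), 0)                       # m = 0
  expect_equal(hamiltonian(0:100, p), hamiltonian(100:0, p))  # F = 0 symmetry
})

test_that("transition rates obey the irrational and rational limits", {
  p0 <- model_params(beta = 0, gamma = 1, N = 10)
  expect_equal(transition_rate(c(-3, 0, 7), p0), rep(0.5, 3))
  pr <- model_params(beta = 1e6, gamma = 1, N = 10)
  expect_equal(transition_rate(-1, pr), 0, tolerance = 1e-12)
  expect_equal(transition_rate(1, pr), 1, tolerance = 1e-12)
  expect_equal(transition_rate(0, model_params(gamma = 2, N = 10)), 1)
  pa <- model_params(beta = 2, gamma = 3, N = 10)
  expect_equal(transition_rate(0.5, pa, "arrhenius"), 3 * exp(1))
})

test_that("propensities have absorbing-free boundaries and mass-action form", {
  rt <- propensities(params_fig2())
  expect_equal(rt$birth[rt$N + 1], 0)
  expect_equal(rt$death[1], 0)
  expect_true(all(rt$birth >= 0 & rt$death >= 0))
  # beta = 0: every agent flips at gamma/2
  rt0 <- propensities(model_params(beta = 0, gamma = 1, N = 20))
  expect_equal(rt0$birth, (20 - 0:20) / 2)
  # Kirman: epsilon-only switching at n = 1 of N = 3
  rk <- propensities(kirman_params(epsilon = 1, mu = 0, N = 3))
  expect_equal(rk$birth[2], 2)
  expect_equal(rk$death[2], 1)
})

test_that("logit rates satisfy detailed balance state by state", {
  for (i in 1:5) {
    set.seed(200 + i)
    q <- random_params()
    rt <- propensities(q)
    n <- 0:(q$N - 1)
    lhs <- rt$birth[n + 1] / rt$death[n + 2]
    rhs <- ((q$N - n) / (n + 1)) *
      exp(q$beta * gain("left_to_right", n, q))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("critical rationality is the reciprocal of the scaled coupling", {
  expect_equal(critical_beta(model_params(J = 10, alpha = 0, N = 10)), 0.1)
  expect_equal(critical_beta(model_params(J = 1.5, alpha = 0, N = 10)), 2 / 3)
  expect_equal(critical_beta(model_params(J = 10, alpha = 1, N = 10)), 0.05)
  expect_error(critical_beta(model_params(J = 0, N = 10)), "J must be positive")
})

test_that("mean-field fixed points switch from one to three at beta_c", {
  sub <- mean_field_fixed_points(model_params(F = 0, J = 1.5, beta = 0.5, N = 50))
  expect_equal(nrow(sub), 1)
  expect_equal(sub$m, 0)
  expect_true(sub$stable)
  sup <- mean_field_fixed_points(model_params(F = 0, J = 1.5, beta = 1, N = 50))
  expect_equal(nrow(sup), 3)
  expect_equal(sup$m[2], 0, tolerance = 1e-8)
  expect_equal(sup$m[1], -sup$m[3], tolerance = 1e-8)
  expect_equal(sup$stable, c(TRUE, FALSE, TRUE))
  # strong rationality with a weak field: stable roots near +-1
  hi <- mean_field_fixed_points(model_params(F = 0.5, J = 1.5, beta = 8, N = 50))
  expect_equal(nrow(hi), 3)
  expect_true(all(abs(abs(hi$m[c(1, 3)]) - 1) < 0.05))
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(model_params(gamma = 0, N = 10), "gamma")
  expect_error(model_params(alpha = 1.5, N = 10), "alpha")
  expect_error(model_params(N = 0), "N")
  expect_error(kirman_params(epsilon = 0, mu = 0, N = 5), "at least one")
})
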