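test_that("the unstable point sits between the two modes", {
  # symmetric bistable case: minimum exactly at N/2
  ps <- steady_state(propensities(model_params(F = 0, J = 1.5, beta = 1, N = 40)))
  st <- find_unstable_point(ps)
  expect_equal(st$n_u, 20)
  expect_lt(st$n_minus, st$n_u)
  expect_gt(st$n_plus, st$n_u)
  # subcritical rationality: monomodal, flagged not bistable
  mono <- steady_state(propensities(model_params(F = 0, J = 1.5, beta = 0.5, N = 40)))
  expect_error(find_unstable_point(mono), class = "bd_not_bistable")
})

test_that("closed-form first-passage times equal the linear-system solve", {
  # moderate barriers only: the dense reference solve is limited to passage
  # times within double-precision conditioning (~1e12), unlike the log-space
  # closed forms
  for (p in list(params_fig3(),
                 model_params(F = 0.05, J = 2, beta = 1, N = 40),
                 model_params(F = -0.05, J = 2, beta = 1, N = 30))) {
    rt <- propensities(p)
    nu <- find_unstable_point(steady_state(rt))$n_u
    tau_cf <- mfpt_exact(rt, nu)
    tau_ls <- mfpt_solve(rt, nu)
    expect_equal(tau_cf[nu + 1], 0)
    rel <- abs(tau_cf - tau_ls) / pmax(abs(tau_ls), 1e-12)
    expect_lt(max(rel[-(nu + 1)]), 1e-8)
    # boundary condition: the only move out of n = 0 takes mean time 1/a_1
    expect_equal(tau_cf[2] - tau_cf[1], -1 / rt$birth[1], tolerance = 1e-10)
  }
  expect_error(mfpt_exact(propensities(params_fig3()), 0), "interior")
})

test_that("the splitting probability is harmonic and matches simulation", {
  rt <- propensities(params_fig3())
  st <- find_unstable_point(steady_state(rt))
  phi <- splitting_probability(rt, st)
  expect_gte(phi, 0)
  expect_lte(phi, 1)
  # independent absorbing-boundary linear solve of the harmonic system
  idx <- (st$n_minus + 1):(st$n_plus - 1)
  k <- length(idx)
  M <- matrix(0, k, k)
  rhs <- numeric(k)
  for (r in seq_len(k)) {
    s <- idx[r]
    M[r, r] <- -(rt$birth[s + 1] + rt$death[s + 1])
    if (r > 1) M[r, r - 1] <- rt$death[s + 1]
    if (r < k) M[r, r + 1] <- rt$birth[s + 1]
  }
  rhs[k] <- -rt$birth[idx[k] + 1]  # h(n_plus) = 1
  h <- solve(M, rhs)
  expect_equal(phi, h[match(st$n_u, idx)], tolerance = 1e-10)
  # symmetric field: a coin flip
  rts <- propensities(model_params(F = 0, J = 1.5, beta = 1, N = 40))
  sts <- find_unstable_point(steady_state(rts))
  expect_equal(splitting_probability(rts, sts), 0.5, tolerance = 1e-12)
  # Monte Carlo: absorb at the two modes, count right-mode commitments
  abs_rates <- rt
  for (s in c(st$n_minus, st$n_plus)) {
    abs_rates$birth[s + 1] <- 0
    abs_rates$death[s + 1] <- 0
  }
  nrun <- 2000
  hits <- vapply(seq_len(nrun), function(i) {
    tr <- suppressMessages(ssa_trajectory(abs_rates, st$n_u, 1e9,
                                          seed = 5000 + i))
    tr$states[length(tr$states)] == st$n_plus
  }, logical(1))
  se <- sqrt(phi * (1 - phi) / nrun)
  expect_lt(abs(mean(hits) - phi), 3 * se)
})

test_that("splitting probability is monotone in the field", {
  phis <- vapply(c(-0.05, 0, 0.05, 0.1), function(f) {
    rt <- propensities(model_params(F = f, J = 1.5, beta = 1, N = 50))
    splitting_probability(rt, find_unstable_point(steady_state(rt)))
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("mode escape times reflect the field asymmetry", {
  # F > 0: the right (favoured) mode is much harder to leave
  rt <- propensities(params_fig2())
  ps <- steady_state(rt)
  st <- find_unstable_point(ps)
  esc <- mode_escape_times(rt, ps, st)
  expect_gt(esc$tau_rl, esc$tau_lr)
  expect_equal(sum(esc$rho_l), 1)
  expect_equal(sum(esc$rho_r), 1)
  tau <- mfpt_exact(rt, st$n_u)
  expect_gte(esc$tau_lr, min(tau[1:st$n_u]))
  expect_lte(esc$tau_lr, max(tau[1:st$n_u]))
  # F = 0: symmetric escape
  rts <- propensities(model_params(F = 0, J = 1.5, beta = 1, N = 40))
  pss <- steady_state(rts)
  sts <- find_unstable_point(pss)
  escs <- mode_escape_times(rts, pss, sts)
  expect_equal(escs$tau_lr, escs$tau_rl, tolerance = 1e-8)
})

test_that("the two-state reduction conserves mass and matches the mass split", {
  rt <- propensities(params_fig2())
  pa <- passage_analysis(rt)
  expect_equal(relaxation_rate(0.5, 7, 7), 1 / 7)
  two <- two_state_reduction(pa$phi_R, pa$tau_lr, pa$tau_rl, piL0 = 0.4)
  tt <- c(0, 10, 1e3, 1e5)
  expect_equal(two$pi_L(tt) + two$pi_R(tt), rep(1, 4))
  # started at the stationary mass the solution is constant
  twos <- two_state_reduction(pa$phi_R, pa$tau_lr, pa$tau_rl, piL0 = two$piL_s)
  expect_equal(twos$pi_L(c(0, 100)), rep(two$piL_s, 2))
  # stationary ratio vs the direct steady-state mass split
  nu <- pa$structure$n_u
  mass_ratio <- sum(pa$steady_state$probs[1:nu]) /
    sum(pa$steady_state$probs[(nu + 2):51])
  expect_lt(abs(two$stationary_ratio - mass_ratio) / mass_ratio, 0.1)
  # the approximation slightly underestimates the spectral relaxation time
  # (checked where the spectral gap is resolvable in double precision)
  rt3 <- propensities(params_fig3())
  pa3 <- passage_analysis(rt3)
  expect_lte(1 / pa3$lambda2_approx, operator_spectrum(rt3)$relaxation_time)
})

test_that("the metastable closed form is a signed correction that decays", {
  rt <- propensities(params_fig3())
  pa <- passage_analysis(rt)
  piL0 <- 1 - pa$phi_R
  d <- metastable_distribution(pa$steady_state, pa$structure,
                               pa$lambda2_approx, piL0, t = 50)
  # the correction is a signed vector summing to zero, so mass is conserved
  expect_equal(sum(d$probs - pa$steady_state$probs), 0, tolerance = 1e-12)
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)
  # in the long-time limit the correction vanishes
  dl <- metastable_distribution(pa$steady_state, pa$structure,
                                pa$lambda2_approx, piL0, t = 1e9)
  expect_equal(dl$probs, pa$steady_state$probs, tolerance = 1e-12)
})

test_that("the metastable closed form tracks the full lock-in solution", {
  # strong lock-in chain, start one state right of n_u: the initial mode
  # masses come from the transient solution after the fast relaxation
  rt <- propensities(params_fig2())
  pa <- passage_analysis(rt)
  piL0 <- initial_left_mass(rt, pa$structure, n0 = 25)
  d <- metastable_distribution(pa$steady_state, pa$structure,
                               pa$lambda2_approx, piL0, t = 10)
  full <- suppressMessages(transient_distribution(rt, 25, 10))
  expect_lt(max(abs(d$probs - full$probs)), 0.02)
})

test_that("asymptotic escape exponents are linear in N and the field ratio", {
  p <- model_params(F = 0, J = 1.5, N = 50)
  expect_equal(unname(mfpt_asymptotic_exponent(p)), c(50, 50))
  p3 <- params_fig3()
  ex <- mfpt_asymptotic_exponent(p3)
  expect_equal(unname(ex), c(50 * (1 - 0.025 / 1.5), 50 * (1 + 0.025 / 1.5)),
               tolerance = 1e-12)
  expect_equal(round(unname(ex), 2), c(49.17, 50.83))
  # exact escape-time asymmetry grows linearly in N at strong rationality
  Ns <- seq(20, 60, by = 10)
  gaps <- vapply(Ns, function(N) {
    rt <- propensities(model_params(F = 0.025, J = 1.5, beta = 4, N = N))
    pa <- passage_analysis(rt)
    log(pa$tau_rl) - log(pa$tau_lr)
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
  fit <- stats::lm(gaps ~ Ns)
  expect_gt(summary(fit)$r.squared, 0.95)
})
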