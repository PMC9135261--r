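make_dataset <- function(n_traj = 20, seed = 1, horizon = 400, points = 40,
                         params = params_fig3(), n0 = 25) {
  rt <- propensities(params)
  grid <- seq(horizon / points, horizon, length.out = points)
  do.call(rbind, lapply(seq_len(n_traj), function(i) {
    tr <- ssa_trajectory(rt, n0, horizon, seed = seed * 1000 + i)
    data.frame(trajectory_id = i, time = c(0, grid),
               n = c(n0, sample_on_grid(tr, grid)))
  }))
}

test_that("t = 0 observations act as exact initial conditions", {
  dat <- data.frame(trajectory_id = 1, time = 0, n = 25)
  expect_equal(negative_log_likelihood(dat, c(0.025, 1.5, 1), N = 50), 0)
  # without a t = 0 row and without n0 the policy errors out
  dat2 <- data.frame(trajectory_id = 1, time = 5, n = 20)
  expect_error(negative_log_likelihood(dat2, c(0.025, 1.5, 1), N = 50),
               "initial condition")
  expect_gt(negative_log_likelihood(dat2, c(0.025, 1.5, 1), N = 50, n0 = 25), 0)
})

test_that("the likelihood is exactly invariant along the beta scaling", {
  dat <- make_dataset(n_traj = 5, seed = 4)
  base <- negative_log_likelihood(dat, c(0.025, 1.5, 1), N = 50, beta = 1)
  for (cc in c(0.5, 2, 5)) {
    scaled <- negative_log_likelihood(dat, c(0.025 / cc, 1.5 / cc, 1), N = 50,
                                      beta = cc)
    expect_equal(scaled, base, tolerance = 1e-10)
  }
  # alpha scaling: (1 + alpha) multiplies the effective coupling
  with_alpha <- negative_log_likelihood(dat, c(0.025, 0.75, 1), N = 50,
                                        beta = 1, alpha = 1)
  expect_equal(with_alpha, base, tolerance = 1e-10)
})

test_that("the truth beats a mis-specified coupling on synthetic data", {
  dat <- make_dataset(n_traj = 50, seed = 8)
  nll_true <- negative_log_likelihood(dat, c(0.025, 1.5, 1), N = 50)
  nll_bad <- negative_log_likelihood(dat, c(0.025, 3.0, 1), N = 50)
  expect_lt(nll_true, nll_bad)
})

test_that("the spectral likelihood equals a matrix-exponential likelihood", {
  p <- model_params(F = 0.1, J = 1, beta = 1, N = 15)
  dat <- make_dataset(n_traj = 3, seed = 2, horizon = 10, points = 5,
                      params = p, n0 = 7)
  got <- negative_log_likelihood(dat, c(0.1, 1, 1), N = 15)
  # independent evaluation: expm marginals, observation by observation
  rt <- propensities(p)
  want <- 0
  for (r in which(dat$time > 0)) {
    pr <- oracle_expm(rt, 7, dat$time[r])[dat$n[r] + 1]
    want <- want - log(max(pr, 1e-300))
  }
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("error metrics reproduce their closed forms", {
  expect_equal(calibration_errors(c(0.025, 1.5, 1), c(0.025, 1.5, 1)),
               c(E_tot = 0, f = 0))
  expect_equal(calibration_errors(c(0.025, 1.5, 1.0), c(0.05, 1.5, 1.0)),
               c(E_tot = 1, f = 1))
  # doubling F and J together preserves the ratio
  err <- calibration_errors(c(0.025, 1.5, 1.0), c(0.05, 3.0, 1.0))
  expect_equal(unname(err["f"]), 0)
  expect_equal(unname(err["E_tot"]), 2)
  expect_error(calibration_errors(c(0, 1, 1), c(1, 1, 1)), "non-zero")
})

test_that("calibration is deterministic under a fixed seed", {
  dat <- make_dataset(n_traj = 3, seed = 6, horizon = 100, points = 10)
  prob <- calibration_problem(dat, N = 50, population = 8, generations = 4,
                              seed = 99)
  f1 <- suppressMessages(calibrate(prob))
  f2 <- suppressMessages(calibrate(prob))
  expect_identical(f1$theta_star, f2$theta_star)
  expect_identical(f1$nll_star, f2$nll_star)
  expect_true(f1$theta_star["F"] >= -2 && f1$theta_star["F"] <= 2)
  expect_true(f1$theta_star["J"] >= exp(-2) && f1$theta_star["J"] <= exp(2))
  expect_true(f1$theta_star["gamma"] >= exp(-1) &&
                f1$theta_star["gamma"] <= exp(1))
  expect_error(calibration_problem(dat, N = 50, population = 2), "population")
})

test_that("the data-requirement experiment tabulates all three protocols", {
  res <- suppressMessages(experiment_data_requirements(list(
    N = 30, n0 = 15, horizon = 100, n_points = 10,
    horizons = c(50, 100), points_grid = c(5, 10), counts = c(1, 3),
    population = 6, generations = 3, seed = 2, max_tries = 400,
    theta_true = c(F = 0.025, J = 1.5, gamma = 1))))
  expect_s3_class(res, "data.frame")
  expect_setequal(names(res),
                  c("protocol", "condition", "value", "E_tot", "f",
                    "nll_star", "seed"))
  expect_equal(nrow(res), 2 + 2 + 2 + 2)
  expect_setequal(unique(res$protocol), c("i", "ii", "iii"))
  expect_true(all(res$E_tot >= 0 & res$f >= 0))
})
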