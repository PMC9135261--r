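# bdchoice

Exact time-dependent analysis of collective binary decisions — and of any
finite one-step birth-death chain — in R.

A population of `N` agents each holds one of two choices. Every agent feels
the shared influence `I(n) = F + J m(n)`, where `m(n) = (2n − N)/N` is the
average opinion, `F` an exogenous field (prices, news, advertising) and `J`
the strength of conformity; a flip changes the generalised utility by

```
G = −2 S (F + J m(n) (1 + α)) + 2 (1 + α) J / N
```

with `α ∈ [0, 1]` interpolating selfish → altruistic agents, and flips occur
at the logit (Glauber) rate `γ / (1 + exp(−β G))` with rationality `β`.
Aggregated, this is a birth-death master equation `dP/dt = A P` on
`n = 0 … N`, the same chain that describes mean-field Ising spins, Kirman's
recruiting ants (also supported directly), and two-state gene expression.

The package provides, exactly and at scale `N` of a few hundred:

* **Transient distributions** `P(n, t | n0)` by the spectral resolvent
  method — eigenvalues only, no eigenvectors — with scaled polynomial
  recursions, complex pseudospectrum handling, and an automatic
  matrix-exponential fallback for degenerate spectra
  (`transient_distribution()`, `transient_from_mixture()`).
* **Steady states** in closed form from Kirchhoff's theorem
  (`steady_state()`), equal to binomially weighted Boltzmann factors
  `C(N,n) exp(β H(n))/Z` for the logit family.
* **Stochastic simulation**: exact Gillespie trajectories and reproducible
  ensembles with a compiled inner loop (`ssa_trajectory()`,
  `ssa_ensemble()`).
* **Metastability / lock-in analysis**: unstable point, exact mean
  first-passage times in log-space, splitting probability, and the two-state
  approximation `λ₂ ≈ φ_R/τ_lr + (1 − φ_R)/τ_rl` of the relaxation rate
  (`passage_analysis()` and friends).
* **Calibration**: a composite likelihood built from the exact transient
  solution, minimised by a seeded differential-evolution search over
  `{F, J, γ}` (`negative_log_likelihood()`, `calibrate()`), with the
  data-requirement experiments (`experiment_data_requirements()`).

## Worked example

The weak-field bistable society: `F = 0.025`, `J = 1.5`, `α = 0`, `β = 1`,
`γ = 1`, `N = 50`. Conformity dominates the field, so agents lock into
either collective choice and the sub-optimal lock-in is long-lived.

```r
library(bdchoice)

params <- model_params(F = 0.025, J = 1.5, alpha = 0, beta = 1, gamma = 1, N = 50)
rates  <- propensities(params)

operator_spectrum(rates)
#> Spectrum of 51 x 51 master operator
#>   lambda2 = -0.000775939+0i, relaxation time 1/|Re lambda2| = 1288.76

passage_analysis(rates)
#> Metastability analysis
#>   modes: n_minus = 3, n_u = 24, n_plus = 47
#>   phi_R = 0.534187
#>   tau_lr = 767.364, tau_rl = 5464.59
#>   lambda2 (two-state approx) = 0.000781375, 1/lambda2 = 1279.8
#>   stationary masses: pi_L = 0.1091, pi_R = 0.8909
```

Reading: the steady state is bimodal with modes at `n = 3` and `n = 47`
separated by the unstable point `n = 24`. Starting at the unstable point the
society commits right (the choice favoured by `F > 0`) with probability
0.534; escaping the left mode takes on average 767 time units against 5465
for the favoured right mode, and combining these with the splitting
probability gives a relaxation time of 1279.8 — within 0.7% of, and slightly
below, the exact spectral value 1288.76, because the two-state reduction
ignores the fast initial relaxation into the modes.

Calibration from synthetic data at the same truth (200 SSA realisations
observed at 100 points on `[0, 2000]`):

```r
fx  <- generate_fixture("calibration", seed = 1, out_dir = tempdir())
dat <- attr(fx, "data")
fit <- calibrate(calibration_problem(dat, N = 50, population = 30,
                                     generations = 80, seed = 1))
fit
#> Calibration: F* = 0.02607, J* = 1.498, gamma* = 0.9163 (NLL = 57066.0)
calibration_errors(c(0.025, 1.5, 1), fit$theta_star)
#>     E_tot         f
#> 0.1291338 0.0450011
```

All three parameters are recovered with a total relative error of 0.13 and a
field-to-coupling ratio error of 0.05. The likelihood is exactly invariant
under `β`-rescaling (`βF` and `β(1+α)J` are the identifiable combinations),
so `β` and `α` are fixed during calibration.

A thin command-line front end ships at
`system.file("cli", "bdchoice.R", package = "bdchoice")` with subcommands
`solve`, `steady`, `spectrum`, `simulate`, `passage`, `calibrate` and
`fixtures`, driven by a YAML config (see `?read_config`).

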