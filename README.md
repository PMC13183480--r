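# tqreg — regularized quantile regression with tensor covariates

`tqreg` fits linear quantile regression models whose covariates include a
full tensor (an image, a surface grid, a spatiotemporal array) alongside
ordinary scalar covariates:

    Q_tau(Y | x, Z) = alpha + x'beta + <Z, Gamma>

Here `Q_tau` is the conditional tau-quantile, `Z` is a q-way tensor
covariate and `Gamma` its effect, constrained to a low-rank Tucker
decomposition `Gamma = [[Lambda; Gamma^(1), ..., Gamma^(q)]]` so that a
64 x 64 coefficient image costs ~130 parameters at rank (2,2) instead
of 4096. It is aimed at researchers relating scalar outcomes (clinical
scores, behavioral measures) to imaging-derived arrays when the response
is skewed, heavy-tailed or heteroskedastic — the situations where
least-squares tensor regression breaks down and quantile loss does not.

What makes the approach distinctive:

* **Smoothed check loss.** The non-differentiable quantile loss
  `rho_tau(u) = (tau - 1{u<0}) u` is replaced by a generalized Huber
  surrogate `H_{tau,nu}` (linear–quadratic–linear, uniform gap
  `<= nu * max(tau, 1-tau)^2 / 2`), annealed along a geometric schedule
  `nu -> 0`.
* **Cyclic block relaxation.** The model is linear in each of the
  `q + 2` parameter blocks — `(alpha, beta)`, the core `Lambda`, each
  factor `Gamma^(j)` — with the others fixed; blocks are updated
  cyclically by Barzilai–Borwein gradient descent with an Armijo
  safeguard, and the penalized objective provably never increases across
  a block update. Stages stop on a 0.01% relative-change rule.
* **Penalties through the composed effect.** Lasso and fused-lasso
  penalties apply to the assembled tensor `Gamma`, not to the
  decomposition components, so spatial regularization acts on the
  coefficient map a scientist actually interprets. Fused-lasso adjacency
  supports order-3 grids with wraparound in the last mode and no fusion
  across mode-1 slices (e.g. left/right hemisphere blocks).
* **Model selection.** Rank by BIC with a Tucker-aware degrees-of-freedom
  count; penalty weight by K-fold cross-validation on held-out check
  loss.
* **Seeded simulation suite.** Binary image signals (square, cross, disk,
  triangle, star), four error families (normal, t, Cauchy, chi-squared)
  scaled to a target SNR, plus an order-3 surface-style fixture for the
  fused lasso.

## Worked example

Recover a cross-shaped 32 x 32 signal from n = 500 subjects under Cauchy
noise — the regime where the quantile loss earns its keep:

```r
library(tqreg)

spec <- tqr_sim_spec(signal = "cross", p = 32, n_train = 500,
                     n_test = 250, snr = 3, family = "cauchy", seed = 7)
sim <- simulate_tqr(spec)

fit <- tqr_fit(sim$train, tqr_control(rank = c(2, 2), seed = 8,
                                      n_restarts = 1))
fit
#> Tensor quantile regression fit (tau = 0.5 )
#>   rank ( 2, 2 ), final objective 93.0028
#>   sweeps: 18 ; converged: TRUE

evaluate_fit(fit, sim$truth, sim$test)
#> $test_mae
#> [1] 12.68306
#> $gamma_rmse
#> [1] 0.1618958

round(fit$model$beta, 2)
#> [1] 0.85 1.84 2.75 3.35 4.79   # truth: 1 2 3 4 5
```

The effect estimate has root-mean-squared error 0.16 per cell against
0.50 for the null (all-zero) estimate, and the scalar effects land near
their true values — despite errors with no finite mean. The test MAE
(12.7) is dominated by the Cauchy noise itself, not by estimation error.
A least-squares fit of the identical model on the identical data
(`loss_family = "squared"`) returns `gamma_rmse` 95.8: the mean
regression is destroyed by the heavy tails, the median regression is
not. Under normal errors the two agree closely.

Regularization and selection:

```r
adj <- grid_adjacency(c(2, 75, 50), wrap_mode3 = TRUE)   # surface grids
pen <- penalty_spec("fused_lasso", lambda = 0.002, adjacency = adj)
cv  <- cv_lambda(data, lambdas = c(0, 0.002, 0.006), K = 5, control = ctl)
rk  <- select_rank(data, candidates = 1:4, control = ctl)
```

A thin command-line driver (`inst/cli/tqr`) exposes
`simulate | fit | predict | evaluate | cv-lambda | select-rank` over JSON
configs and plain-text dataset containers; see `?tqr_cli`.

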