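# emels

Extended mixed-effect location-scale models for forecasting intensive
longitudinal data (daily diaries, EMA): longitudinal mixed models in which
every person has not only their own **level**, but also their own
**within-person residual variance** and their own **lag-1
autocorrelation**, all three treated as correlated normal random effects.

For person *i* with equally spaced occasions,

    y_i = X_i β + 1 τ_i + ε_i,        ε_i  stationary AR(1) with
    σ²_i = exp(s0 + ω_i),   ρ_i = tanh(r0 + ι_i),
    (τ_i, ω_i, ι_i) ~ N(0, Φ),   Φ a free 3×3 covariance,

so the residual covariance of person *i* is
`σ²_i/(1−ρ_i²) · ρ_i^|j−k|`. The marginal likelihood integrates the three
random effects out by mode-adapted Gauss–Hermite quadrature and is
maximized with the analytic score on an unconstrained (log-Cholesky)
parametrization.

Who this is for: anyone building person-level prediction models from
many short time series — forecasting tomorrow's symptom score, affect
rating, or behaviour for (Task 1) a person in the training sample,
(Task 2) a new person with no history, or (Task 3) a new person whose
history is available, via

    ŷ_{i,T+H} = x'β̂ + τ̂_i + ρ̂_i^H ε̂_{i,T}.

The package also provides the two machine-learning hybrids of this model:

* **`emels_lasso()` / `lambda_path()`** — L1-penalized fixed effects by
  block coordinate descent (proximal gradient + soft-thresholding for β,
  quasi-Newton for the variance block), a warm-started penalty path with
  AIC/BIC selection, and an unpenalized refit on the selected support;
* **`emels_tree()`** — an alternating regression-tree variant: CART (via
  rpart, with 10-fold CV cost-complexity pruning) on random-effect-freed
  residuals, then the location-scale model on the leaf-membership dummies,
  iterated to convergence.

Plus `mem_ar1()` (the nested AR(1) linear mixed model, fitted by direct
marginal-normal ML), empirical-Bayes random effects (`ranef()`,
`eb_estimate()`), forecast-error variances, forecast evaluation
(`evaluate_forecasts()`, `forecast_benchmark()`), long-format CSV IO with
validation and preprocessing, and seed-deterministic EMA-style data
generators (`simulate_emels_data()`, `simulate_tree_data()`).

## Worked example

```r
library(emels)

sim <- simulate_emels_data(I = 80, T_len = 40, beta = c(2, 0.4),
                           s0 = -0.5, r0 = 0.3,
                           Phi = diag(c(0.9, 0.4, 0.3)), seed = 42)
sp  <- split_train_test(sim, n_train_persons = 60, n_train_times = 39)

fit <- emels(y ~ x1, sp$train, Q = 4)   # Q = 10 for final fits
summary(fit)
#> Extended mixed-effect location-scale model (E-MELS)
#>   persons: 60, observations: 2340
#>   logLik: -2968.21  AIC: 5956.419  BIC: 6013.998
#> ...
#> Parameter table (reporting scale):
#>                               parameter estimate     se
#>                             (Intercept)   1.9241 0.1875
#>                                      x1   0.4035 0.0050
#>                      intercept variance   1.2478 0.2388
#>                residual variance (mean)   0.6080 0.0489
#>  residual variance (between-person var)   0.3591 0.0752
#>                  autocorrelation (mean)   0.2649 0.0561
#>    autocorrelation (between-person var)   0.1948 0.0427
```

The generating values (intercept 2, slope 0.4, intercept variance 0.9,
`exp(-0.5) = 0.61`, variance 0.4, `tanh(0.3) = 0.29`, variance 0.3) are
recovered within sampling error: the residual-variance and autocorrelation
rows are the location-scale part — the mean person's residual variance is
0.61 with substantial between-person spread (0.36 on the log scale), and
the mean autocorrelation 0.26 varies across persons (0.19 on the atanh
scale).

Does the location-scale extension beat the ordinary AR(1) mixed model?

```r
anova(fit, mem_ar1(y ~ x1, sp$train))
#>        df  logLik    AIC    BIC  Chisq Chi Df Pr(>Chisq)
#> nested  5 -3247.7 6505.3 6534.1
#> full   10 -2968.2 5956.4 6014.0 558.91      5  < 2.2e-16 ***
```

One-step-ahead forecasts for the held-out last occasion of each training
person (Task 1), with person-specific autocorrelations applied to the last
residual:

```r
fc <- forecast(fit, sp$test_task1, task = 1)
evaluate_forecasts(fc)
#> Task-1 one-step MSE: 1.054 (SE 0.236), mean sigma_F: 0.933
```

`forecast(..., task = 2)` and `forecast(..., task = 3, history = ...)`
handle new persons; `forecast_benchmark()` produces the full
model-by-task accuracy/precision table.

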