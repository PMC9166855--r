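---
title: "Location-scale mixed models for forecasting intensive longitudinal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location-scale mixed models for forecasting intensive longitudinal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Daily-diary and EMA studies produce many short, equally spaced time series,
one per person. Three kinds of between-person differences matter for
forecasting such data: people differ in their *level*, in their
*within-person variability*, and in how strongly consecutive days are
*autocorrelated*. The model this package fits treats all three as random
effects.

For person $i$ with $T_i$ occasions,

$$y_i = X_i \beta + 1_{T_i}\tau_i + \epsilon_i,$$

where $\epsilon_i$ is a stationary AR(1) process with person-specific
parameters

$$\sigma^2_{\epsilon_i} = \exp(s_0 + \omega_i), \qquad
  \rho_i = \tanh(r_0 + \iota_i),$$

so the residual covariance is
$\Sigma_i = \frac{\sigma^2_{\epsilon_i}}{1-\rho_i^2}\,
 \big[\rho_i^{|j-k|}\big]_{jk}$ (stationary variance on the diagonal).
The exp and tanh links keep the variance positive and the autocorrelation in
$(-1, 1)$ on an unconstrained scale. The random vector
$v_i = (\tau_i, \omega_i, \iota_i)$ is normal with mean zero and a *free*
$3\times 3$ covariance $\Phi$, so level, volatility and inertia may
correlate. Setting $\mathrm{var}(\omega) = \mathrm{var}(\iota) = 0$ recovers
the ordinary random-intercept model with AR(1) errors (`mem_ar1()`), which
is the natural null model: `anova()` between the two fits is a 5-df
likelihood-ratio test (two variances plus three covariances).

Only the random-intercept mean structure is implemented ($Z_i = 1_{T_i}$,
$k = 1$). That is the configuration used in every analysis this package is
designed around; the quadrature kernel is specialized to it.

## Estimation

The marginal likelihood integrates $v_i$ out of
$f(y_i \mid v_i)\,f(v_i \mid \Phi)$ per person, a 3-dimensional integral
with no closed form. We use mode-adapted Gauss–Hermite quadrature: per
person, the posterior mode of $v_i$ and the curvature there recentre and
rescale a $Q^3$ product rule. The integrand touches the data only through
five scalar sums of the fixed-effect residuals, so a whole node block is a
few vectorized operations; the AR(1) inverse is tridiagonal, giving $O(T_i)$
determinants and quadratic forms throughout.

The outer maximization runs a quasi-Newton method on the unconstrained
parameters $(\beta, s_0, r_0, \text{log-Cholesky of }\Phi)$ with the
analytic score (exact for the fixed node set, by differentiating the
log-sum of node weights). Between runs the per-person adaptation is
refreshed; once the modes move less than `freeze_tol` (default 0.01) the
adaptation is frozen so the remaining iterations maximize one fixed smooth
surface. Without freezing, the alternation between "refresh nodes" and
"maximize" orbits the joint fixed point in slowly damped oscillations; with
it, the trace is monotone and convergence is declared on the relative
log-likelihood change (`tol`, default `1e-6`). A consequence worth knowing:
the ML estimate is reproducible up to the adaptation accuracy (about
`1e-4` in the parameters when refitting from the solution), not to machine
precision — a property of mode-adapted quadrature, not of the optimizer.

Tunable settings and defaults:

* `Q` (nodes per dimension): default 10. On the designs in this vignette,
  estimates changed by less than 0.01 between `Q = 4` and `Q = 8`, so the
  test suite and the acceptance script run at `Q = 4`; keep 10 for final
  reported fits.
* Initialization: pooled OLS for $\beta$; $s_0$ from the pooled residual
  variance; $r_0$ from the pooled lag-1 residual autocorrelation (clipped
  to $|\rho| \le 0.95$); $\Phi = 0.1 I$.
* Numerical guards: the exponent $s_0 + \omega$ is clipped to $\pm 30$
  before `exp` (3-d quadrature tails can be extreme), the atanh argument
  to $\pm 18$; the log-Cholesky parametrization keeps $\Phi$ positive
  definite by construction, all prior computations run in the whitened
  frame $u = L^{-1}v$ (stable even for near-singular $\Phi$), and a smooth
  quadratic barrier activates when a log-diagonal of $L$ falls below $-6$
  — a conditional-SD floor of $e^{-6}$, scientifically zero, that keeps
  the optimizer out of the razor-thin valley a collapsing factor creates
  (curvature there grows like $1/L_{jj}^2$, which finite quasi-Newton
  steps cannot traverse; a barrier is used rather than box bounds because
  the bounded optimizer converges far more slowly even when no bound is
  active). With several correlated random effects and
  little data, the marginal likelihood can have multiple local optima in
  $\Phi$; refitting from another start is the practical check.
* Standard errors come from the observed information (central differences
  of the analytic score at the optimum, holding the final adaptation
  fixed), delta-transformed to the reporting scale
  ($\exp(\hat s_0)$, $\tanh(\hat r_0)$, the $\Phi$ variances).

Occasions must be consecutive integers within person; gaps are a hard
error, because $\rho^{|j-k|}$ silently changes meaning on a gapped grid.

## Forecasting

Three prediction tasks, all one formula:

$$\hat y_{i,T_i+H} = x_{i,T_i+H}'\hat\beta + \hat\tau_i
  + \hat\rho_i^{\,H}\,\hat\epsilon_{i,T_i}.$$

* **Task 1** (trained person): $\hat\tau_i$ and the last level-1 residual
  $\hat\epsilon_{i,T_i}$ come from the training fit.
* **Task 2** (new person, no history): only $x'\hat\beta$.
* **Task 3** (new person with history): random effects are first estimated
  from the person's history at the training parameters, then the Task-1
  formula applies.

Random effects are estimated by empirical Bayes: the posterior *mean* of
$v_i$ under the person's adapted quadrature rule (the mean, not the mode,
because it reduces exactly to the BLUP
$\hat b_i = \Phi Z_i'V_i^{-1}(y_i - X_i\hat\beta)$ in the linear special
case). The person-specific $\hat\rho_i = \tanh(\hat r_0 + \hat\iota_i)$ is
what distinguishes a location-scale forecast from an ordinary mixed-model
forecast in Task 1/3.

Forecast-error variances treat the EB variance/autocorrelation as known
plug-ins: for Tasks 1/3 the fixed-effect uncertainty term (with the GLS
shrinkage weight), the random-effect prediction variance
$\phi^2_\tau - \phi^4_\tau 1'V^{-1}1$, and the unconditional stationary
residual variance $\sigma^2_{\epsilon_i}/(1-\rho_i^2)$; for Task 2 the
unshrunk version. The future residual variance enters unconditionally
(not reduced by conditioning on observed residuals) — deliberately, to
match the standard decomposition this package reports. Uncertainty in
$\hat\omega_i, \hat\iota_i$ is not propagated. No forecast-error variance
is reported for tree models; there is no established one.

`evaluate_forecasts()` reports the MSE, its standard error (SD of the
squared errors over $\sqrt m$), and the mean forecast-error SD
$\hat\sigma_F$; `forecast_benchmark()` assembles the model-by-task table.

## The Lasso variant

`emels_lasso()` maximizes $\log L(\theta) - \lambda\sum_{j=1}^p |\beta_j|$
(slopes only; intercept, $s_0$, $r_0$, $\Phi$ unpenalized) by block
coordinate descent: proximal-gradient steps with soft-thresholding for
$\beta$ — zeros are produced bit-exactly by the proximal map — followed by
a sign-constrained quasi-Newton polish on the active set, then a
quasi-Newton step for $(s_0, r_0, \Phi)$, with the quadrature adaptation
refreshed then frozen as above. `lambda_path()` walks an increasing grid
(default 50 values on $[0, 500]$) with warm starts and selects $\lambda$
by AIC or BIC with $\mathrm{df}_\lambda = \#\{\beta_j \ne 0\} +
\dim(\Phi)$ and $n = \sum_i T_i$. The criteria use the *unpenalized*
log-likelihood at the penalized estimate: plugging the penalized objective
in literally makes both criteria monotone in $\lambda$ toward 0, which
destroys selection — this was a genuinely open reading, resolved in favour
of the behaviour the method is known for (and the standard choice in
penalized-mixed-model software). Because the L1 penalty is
scale-sensitive, predictors should be standardized first
(`preprocess_predictors(standardize = TRUE)`, population-SD convention,
recorded for replay); a warning fires otherwise. After selection,
`refit_selected()` refits the unpenalized model on the surviving support —
the refit, not the shrunken fit, feeds forecasting.

## The tree variant

`emels_tree()` alternates (1) a CART regression tree (grown by `rpart`
with `cp = 0.001`, `minsplit = 20`, `minbucket = floor(minsplit/3)`, then
cost-complexity pruned to the subtree minimizing 10-fold CV error, no 1-SE
rule; folds drawn over rows with a recorded seed) on the
random-effect-freed residuals $y_i - \hat\tau_i$, and (2) the
location-scale model refit on the tree's leaf-membership dummies (one
dummy per leaf, no intercept), which re-estimates the leaf means together
with all variance parameters and updates $\hat\tau_i$. The tree is regrown
*and repruned* at every alternation (the two-step loop is applied
literally); iteration stops when the model log-likelihood changes by less
than `tol` (relative, default `1e-4`) or after `max_alt` alternations —
two to four alternations typically suffice. Observations of one person may
fall in different leaves, since the predictors are time-varying. New rows
are routed by replaying the fitted split rules, which the tests verify
against `rpart`'s own predictions; tie-breaking between exactly equal
splits is therefore `rpart`'s (ties have probability zero under the
continuous generators used here). With all random-effect variances at
zero the first alternation already reproduces a plain CART fit.

## The synthetic-data generators

`simulate_emels_data()` draws exactly the model's generative structure:
$v_i \sim N(0, \Phi)$, uniform $[0, 10]$ predictors (redrawn every
occasion by default; per-person by flag), stationary AR(1) residuals
initialized from the stationary distribution. `simulate_tree_data()` is
the benchmark scenario used throughout the tests: nine i.i.d. uniform
$[0, 10]$ predictors per observation, a 4-leaf step function on
$(x_1, x_2, x_3)$ with split point 5 and leaf means 10, 11, 12, 13, plus
$\tau_i$, and AR(1) residuals at $s_0 = -0.67$, $r_0 = 0.26$ with
random-effect variances $(1.0, 0.5, 0.5)$ and zero covariances. Although
only $\tau_i$ appears in the mean, all three person-level differences are
present: $\omega_i$ and $\iota_i$ enter through the residual process, so
held-out persons differ in level, volatility and inertia alike. Both
generators return the generating truths
(per-person $v_i$, leaf assignments) as an attribute and are
seed-deterministic.

What the generators do *not* emulate — and hence what green tests do not
establish about real diary data: bounded ordinal outcomes, missed diary
days (the consecutive-occasion requirement is our alignment convention),
unequally spaced intervals, non-Gaussian random effects, and predictors
that are themselves autocorrelated.

## Problem sizes used by the tests and the acceptance script

The benchmark scenario runs at its stated size ($I = 200$, $T = 51$,
training on $100 \times 50$) with $Q = 4$; the parameter-recovery suite
runs 20 replicates at $I = 200$, $T = 30$; module tests use toy sizes
($I \le 60$) where the property under test is scale-free. One benchmark
fit takes tens of seconds at $Q = 4$ on one core; $Q = 10$ is several
times slower and changes the benchmark estimates by less than 0.01, which
is why the larger suites standardize on $Q = 4$.

Because the benchmark MSEs average 100 squared forecast errors whose
distribution is heavy-tailed (a person two prior SDs out in $\iota$ has
$1/(1-\rho_i^2) \approx 7$), a single simulated replicate carries a
seed-to-seed SD of roughly 0.1 on Tasks 1/3 and 0.4 on Task 2. Comparisons
against single published values should keep that spread in mind.

## Known limitations

* Random intercept only ($k = 1$); no random slopes.
* Plain $\chi^2$ reference for the boundary LR test (no mixture
  correction) — deliberately, to match the standard procedure for this
  model family.
* AGH cost grows as $Q^3$; the fully adaptive variant (modes refreshed
  inside every objective evaluation) is not implemented.
* No missing-data handling: series must be complete and consecutive.
* Ridge/elastic-net penalties, penalties on $\Phi$, random forests and
  conditional inference trees are out of scope.
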