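# ML fitting, standard errors, information criteria, LR test.

fit_cache <- new.env()
small_fit <- function() {
  if (is.null(fit_cache$fit)) {
    fit_cache$sim <- toy_sim(I = 60, T_len = 12, seed = 21,
                             beta = c(2, 0.5), s0 = 0.1, r0 = 0.3,
                             Phi = diag(c(0.8, 0.35, 0.3)))
    fit_cache$fit <- emels(y ~ x1, fit_cache$sim, Q = 4,
                           control = list(tol = 1e-8))
  }
  list(sim = fit_cache$sim, fit = fit_cache$fit)
}

test_that("simulated parameters are recovered within 3 SE on a small run", {
  sf <- small_fit()
  fit <- sf$fit
  expect_true(fit$converged)
  rep_ <- fit$report
  truth <- c(2, 0.5, 0.8, exp(0.1), 0.35, tanh(0.3), 0.3)
  expect_true(all(is.finite(rep_$se)))
  expect_true(all(abs(rep_$estimate - truth) <= 3 * rep_$se))
  # score near zero at the optimum
  g <- emx("agh_loglik")(fit$env, fit$theta, fit$grid, fit$rules,
                         want_grad = TRUE)$grad
  expect_lt(max(abs(g)), 0.5)
  # information-criterion arithmetic
  expect_equal(fit$aic, -2 * fit$logLik + 2 * fit$n_params)
  expect_equal(fit$bic, -2 * fit$logLik + log(fit$n_total) * fit$n_params)
  expect_equal(fit$n_params, 2 + 2 + 6)
})

test_that("reporting scale round-trips to the raw parameters", {
  fit <- small_fit()$fit
  rep_ <- fit$report
  est <- function(nm) rep_$estimate[rep_$parameter == nm]
  expect_equal(log(est("residual variance (mean)")), fit$s0)
  expect_equal(atanh(est("autocorrelation (mean)")), fit$r0)
  expect_equal(est("intercept variance"), fit$Phi[1, 1])
  expect_equal(est("residual variance (between-person var)"), fit$Phi[2, 2])
  expect_equal(est("autocorrelation (between-person var)"), fit$Phi[3, 3])
})

test_that("refitting from the solution is a stable fixed point", {
  # the refit re-derives the per-person quadrature adaptation from scratch,
  # so the solution is reproducible up to the mode-adaptation accuracy
  # (freeze_tol), not to machine precision
  sf <- small_fit()
  refit <- emels(y ~ x1, sf$sim, Q = 4, se = FALSE, init = sf$fit$theta,
                 control = list(tol = 1e-8))
  expect_lt(max(abs(emx("theta_pack")(refit$theta) -
                      emx("theta_pack")(sf$fit$theta))), 5e-4)
  expect_equal(refit$logLik, sf$fit$logLik, tolerance = 1e-6)
})

test_that("person order does not change the fit", {
  sim <- toy_sim(I = 30, T_len = 15, seed = 22)
  d <- as.data.frame(sim)
  perm <- d[order(match(d$id, rev(unique(d$id))), d$time), ]
  ldp <- long_data(perm, "y", "id", "time", "x1")
  f1 <- emels(y ~ x1, sim, Q = 4, se = FALSE, control = list(tol = 1e-8))
  f2 <- emels(y ~ x1, ldp, Q = 4, se = FALSE, control = list(tol = 1e-8))
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_lt(max(abs(f1$beta - f2$beta)), 1e-4)
  expect_lt(max(abs(f1$Phi - f2$Phi)), 1e-4)
})

test_that("outer progress is monotone up to tolerance", {
  fit <- small_fit()$fit
  tr <- fit$trace
  expect_true(all(diff(cummax(tr)) >= 0))
  expect_true(all(diff(tr) > -1e-3 * (abs(tr[-1]) + 1)))
})

test_that("the AR(1)-LMM special case nests inside the full model", {
  sim <- toy_sim(I = 25, T_len = 10, seed = 23,
                 Phi = diag(c(0.7, 1e-12, 1e-12)), s0 = 0.2, r0 = 0.25)
  lmm <- mem_ar1(y ~ x1, sim)
  expect_true(lmm$converged)
  # likelihood equivalence at the LMM solution with pinned variances
  th <- theta_for(lmm$beta, lmm$s0, lmm$r0,
                  diag(c(lmm$Phi[1, 1], 1e-12, 1e-12)))
  m <- toy_machine(y ~ x1, sim, Q = 6)
  expect_equal(agh_ll(m, th)$ll, lmm$logLik, tolerance = 1e-3,
               ignore_attr = TRUE)
  # rho generated at 0 is recovered near 0
  sim0 <- toy_sim(I = 40, T_len = 12, seed = 24, r0 = 0,
                  Phi = diag(c(0.7, 1e-12, 1e-12)))
  lmm0 <- mem_ar1(y ~ x1, sim0)
  se_r0 <- sqrt(lmm0$vcov_unconstrained[4, 4])
  expect_lt(abs(tanh(lmm0$r0)), 3 * se_r0 * (1 - tanh(lmm0$r0)^2) + 0.02)
})

test_that("likelihood-ratio test has the right df and arithmetic", {
  sf <- small_fit()
  full <- sf$fit
  nested <- mem_ar1(y ~ x1, sf$sim)
  lt <- lr_test(full, nested)
  expect_equal(lt$df, 5)
  expect_equal(lt$statistic, 2 * (full$logLik - nested$logLik),
               tolerance = 1e-6)
  expect_gte(lt$statistic, 0)
  # identical fits: statistic 0, p = 1
  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  a <- anova(full, nested)
  expect_equal(a$Chisq[2], lt$statistic)
})

test_that("standard errors shrink roughly as 1/sqrt(I)", {
  f1 <- mem_ar1(y ~ x1, toy_sim(I = 30, T_len = 8, seed = 25))
  f2 <- mem_ar1(y ~ x1, toy_sim(I = 120, T_len = 8, seed = 26))
  expect_true(all(f1$report$se >= 0, na.rm = TRUE))
  ratio <- f1$report$se[2] / f2$report$se[2]   # slope SE
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})

test_that("fixed-effect SEs match GLS in the degenerate-variance limit", {
  sim <- toy_sim(I = 20, T_len = 10, seed = 27,
                 Phi = diag(c(1e-12, 1e-12, 1e-12)), s0 = 0.1, r0 = 0.2)
  lmm <- mem_ar1(y ~ x1, sim)
  # GLS oracle at the fitted parameters, with the fitted (tiny) phi2_tau
  V_inv_sum <- Reduce(`+`, lapply(emx("emels_env")(
    emx("build_model_input")(y ~ x1, sim)$series)$persons, function(pp) {
      V <- lmm$Phi[1, 1] + dense_ar1(exp(lmm$s0), tanh(lmm$r0), pp$T_len)
      crossprod(pp$X, solve(V, pp$X))
    }))
  se_gls <- sqrt(diag(solve(V_inv_sum)))
  se_fit <- lmm$report$se[1:2]
  expect_equal(se_fit, se_gls, tolerance = 0.02, ignore_attr = TRUE)
})
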