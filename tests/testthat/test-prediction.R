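# Empirical-Bayes estimation, forecasting tasks, error variances,
# evaluation summaries.

pred_cache <- new.env()
pred_fit <- function() {
  if (is.null(pred_cache$fit)) {
    pred_cache$sim <- toy_sim(I = 30, T_len = 12, seed = 31,
                              beta = c(2, 0.4), s0 = 0, r0 = 0.3,
                              Phi = diag(c(0.8, 0.3, 0.25)))
    pred_cache$fit <- emels(y ~ x1, pred_cache$sim, Q = 4)
  }
  list(sim = pred_cache$sim, fit = pred_cache$fit)
}

test_that("EB estimates vanish as the prior degenerates", {
  sim <- toy_sim(I = 3, T_len = 6, seed = 32)
  fit <- emels(y ~ x1, sim, Q = 4, se = FALSE,
               control = list(max_cycles = 1, inner_iter = 0))
  fit$theta$lchol <- emx("lchol_from_phi")(diag(3) * 1e-10)
  fit$Phi <- diag(3) * 1e-10
  v <- emx("eb_core")(fit, sim$y[1:6], fit$env$persons[[1]]$X)
  expect_lt(max(abs(v)), 1e-4)
})

test_that("linear-model EB matches the dense closed form", {
  sim <- toy_sim(I = 15, T_len = 9, seed = 33,
                 Phi = diag(c(0.7, 1e-12, 1e-12)), s0 = 0.1, r0 = 0.25)
  lmm <- mem_ar1(y ~ x1, sim)
  # dense oracle: b = Phi Z' V^{-1} (y - X beta)
  env <- lmm$env
  for (i in c(1, 7, 15)) {
    pp <- env$persons[[i]]
    V <- lmm$Phi[1, 1] + dense_ar1(exp(lmm$s0), tanh(lmm$r0), pp$T_len)
    b_or <- lmm$Phi[1, 1] *
      sum(solve(V, pp$y - drop(pp$X %*% lmm$beta)))
    expect_equal(lmm$eb$tau[i], b_or, tolerance = 1e-8)
    # the AGH posterior mean of the location-scale machinery agrees in the
    # nested case
    obj <- lmm
    obj$model <- "emels"
    obj$theta <- theta_for(lmm$beta, lmm$s0, lmm$r0,
                           diag(c(lmm$Phi[1, 1], 1e-10, 1e-10)))
    obj$Phi <- diag(c(lmm$Phi[1, 1], 1e-10, 1e-10))
    obj$grid <- emx("gh_grid")(8)
    v <- emx("eb_core")(obj, pp$y, pp$X)
    expect_equal(unname(v["tau"]), b_or, tolerance = 1e-4)
  }
})

test_that("EB posterior mean matches a fine-grid integration oracle", {
  sim <- toy_sim(I = 1, T_len = 6, seed = 34)
  fit <- structure(list(model = "emels",
                        theta = theta_for(c(2, 0.5), 0.1, 0.2,
                                          diag(c(0.6, 0.3, 0.25))),
                        Phi = diag(c(0.6, 0.3, 0.25)),
                        s0 = 0.1, r0 = 0.2,
                        grid = emx("gh_grid")(10)), class = "emels")
  m <- toy_machine(y ~ x1, sim)
  pp <- m$env$persons[[1]]
  v_agh <- emx("eb_core")(fit, pp$y, pp$X)
  # brute-force 3-d grid integration of the posterior mean
  gr <- seq(-5, 5, length.out = 81)
  G <- as.matrix(expand.grid(b = gr * sqrt(0.6), om = gr * sqrt(0.3),
                             io = gr * sqrt(0.25)))
  ss <- emx("suffstats")(pp, fit$theta$beta)
  lj <- emx("cond_ll_nodes")(pp, ss, 0.1, 0.2, G)$ll +
    emx("prior_ll_nodes")(G, emx("prior_prep")(fit$Phi))
  w <- exp(lj - max(lj)); w <- w / sum(w)
  v_grid <- colSums(w * G)
  expect_lt(max(abs(unname(v_agh) - unname(v_grid))), 1e-3)
})

test_that("EB intercepts shrink with shorter histories", {
  pf <- pred_fit()
  fit <- pf$fit
  # constant residual pattern: same deviation observed for 1 vs 30 days
  X1 <- matrix(c(1, 5), 1, 2, dimnames = list(NULL, names(fit$beta)))
  mu1 <- drop(X1 %*% fit$beta)
  Xn <- X1[rep(1, 30), , drop = FALSE]
  v_short <- emx("eb_core")(fit, mu1 + 1, X1)
  v_long <- emx("eb_core")(fit, rep(mu1 + 1, 30), Xn)
  expect_lt(abs(v_short["tau"]), abs(v_long["tau"]))
})

test_that("level-1 and random-effect-freed residuals are as defined", {
  pf <- pred_fit()
  fit <- pf$fit
  r1 <- residuals(fit, type = "level1")
  r2 <- residuals(fit, type = "fixed_free")
  yhat <- fitted(fit)
  y <- unlist(lapply(fit$env$persons, `[[`, "y"))
  Xb <- unlist(lapply(fit$env$persons,
                      function(pp) drop(pp$X %*% fit$beta)))
  expect_equal(r1, y - yhat, ignore_attr = TRUE)
  expect_equal(r2, y - (yhat - Xb), ignore_attr = TRUE)
  expect_equal(r2 - r1, Xb, ignore_attr = TRUE)
})

test_that("point forecasts follow the AR(1)-corrected formula", {
  pf <- pred_fit()
  fit <- pf$fit
  idc <- "id"
  ps <- fit$env$persons[[4]]
  pid <- as.character(ps$id)
  eb <- fit$eb[match(pid, fit$eb$id), ]
  for (H in c(1, 2, 5)) {
    fut <- data.frame(id = pid, time = max(ps$times) + H, x1 = 3.3)
    fc <- forecast(fit, fut, task = 1)
    x_fut <- c(1, 3.3)
    eps_T <- ps$y[ps$T_len] - drop(ps$X[ps$T_len, ] %*% fit$beta) - eb$tau
    manual <- drop(x_fut %*% fit$beta) + eb$tau + eb$rho^H * eps_T
    expect_equal(fc$y_hat, manual, tolerance = 1e-10)
    expect_equal(fc$H, H)
  }
  # large horizon: the AR(1) correction dies out
  fut <- data.frame(id = pid, time = max(ps$times) + 400, x1 = 3.3)
  fc_far <- forecast(fit, fut, task = 1)
  expect_equal(fc_far$y_hat, drop(c(1, 3.3) %*% fit$beta) + eb$tau,
               tolerance = 1e-8)
  # task 2 is the fixed part only
  fc2 <- forecast(fit, data.frame(id = "new", time = 99, x1 = 3.3), task = 2)
  expect_equal(fc2$y_hat, drop(c(1, 3.3) %*% fit$beta))
  # empty history is rejected with a pointer to task 2
  expect_error(forecast(fit, fut, task = 3, history = NULL), "task = 2")
})

test_that("one-step forecast is the Gaussian conditional mean when the
           random effects are degenerate", {
  sim <- toy_sim(I = 4, T_len = 8, seed = 35,
                 Phi = diag(c(1e-12, 1e-12, 1e-12)), s0 = 0.1, r0 = 0.35)
  lmm <- mem_ar1(y ~ x1, sim)
  ps <- lmm$env$persons[[2]]
  pid <- as.character(ps$id)
  fut <- data.frame(id = pid, time = 9, x1 = 4.2)
  fc <- forecast(lmm, fut, task = 1)
  # dense conditioning oracle on the joint covariance of the history and
  # the future occasion (random intercept + AR(1) residual, at the fitted
  # parameters): the BLUP forecast must equal the conditional mean
  S <- lmm$Phi[1, 1] + dense_ar1(exp(lmm$s0), tanh(lmm$r0), 9)
  mu_h <- drop(ps$X %*% lmm$beta)
  mu_f <- drop(c(1, 4.2) %*% lmm$beta)
  cond <- mu_f + drop(S[9, 1:8] %*% solve(S[1:8, 1:8], ps$y - mu_h))
  expect_equal(fc$y_hat, cond, tolerance = 1e-6)
})

test_that("forecast-error variances follow the stated decompositions", {
  # Task 2, intercept-only, cov(beta) = 0, phi2_tau = 1, stationary var 1
  expect_equal(emx("fev_task2")(1, matrix(0, 1, 1), 1, 1 - 0.5^2, 0.5), 2)
  # Task 3 variance never exceeds Task 2 for the same person when the
  # fixed-effect uncertainty is switched off
  set.seed(36)
  Xh <- cbind(1, runif(6))
  v13 <- emx("fev_task13")(c(1, 0.4), Xh, matrix(0, 2, 2), 0.9, 0.8, 0.45,
                           H = 1)
  v2 <- emx("fev_task2")(c(1, 0.4), matrix(0, 2, 2), 0.9, 0.8, 0.45)
  expect_lte(v13, v2)
  # dense oracle: independent evaluation with explicit matrices
  phi2 <- 0.7; s2 <- 0.9; rho <- 0.5; H <- 2; Tl <- 3
  covb <- matrix(c(0.05, 0.01, 0.01, 0.02), 2)
  Xh <- cbind(1, c(2, 4, 1)); x_f <- c(1, 3)
  cs <- s2 / (1 - rho^2)
  V <- phi2 * tcrossprod(rep(1, Tl)) + dense_ar1(s2, rho, Tl)
  Cvec <- phi2 * rep(1, Tl) + cs * rho^((Tl + H - 1):H)
  A <- rbind(x_f) - rbind(Cvec) %*% solve(V) %*% Xh
  want <- drop(A %*% covb %*% t(A)) +
    (phi2 - phi2^2 * sum(solve(V) %*% rep(1, Tl))) + cs
  got <- emx("fev_task13")(x_f, Xh, covb, phi2, s2, rho, H = H)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("sigma_F is constant across persons only without location-scale
           heterogeneity", {
  sim <- toy_sim(I = 12, T_len = 10, seed = 37, beta = c(2),
                 Phi = diag(c(0.6, 0.4, 0.3)))
  lmm <- mem_ar1(y ~ 1, sim)
  emx_fit <- emels(y ~ 1, sim, Q = 4)
  fut <- data.frame(id = unique(as.data.frame(sim)$id), time = 11)
  fc_l <- forecast(lmm, fut, task = 1)
  fc_e <- forecast(emx_fit, fut, task = 1)
  expect_lt(diff(range(fc_l$sigma_F)), 1e-8)
  expect_gt(diff(range(fc_e$sigma_F)), 1e-3)
})

test_that("forecast evaluation summarizes accuracy and precision", {
  expect_equal(evaluate_forecasts(c(1, 2), observed = c(1, 4))$mse, 2)
  expect_equal(evaluate_forecasts(c(3, 3), observed = c(3, 3))$mse, 0)
  expect_error(evaluate_forecasts(numeric(0), observed = numeric(0)),
               "no forecasts")
  set.seed(38)
  y <- rnorm(20000)
  ev <- evaluate_forecasts(rep(0, 20000), observed = y)
  expect_lt(abs(ev$mse - 1), 3 * sd(y^2) / sqrt(20000))
  expect_equal(ev$mse_se, sd((y - 0)^2) / sqrt(20000))
})
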