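# Conditional density, AGH marginal likelihood, and the analytic score.

test_that("conditional log-density equals the dense multivariate normal", {
  sim <- toy_sim(I = 4, T_len = 7, seed = 5)
  m <- toy_machine(y ~ x1, sim)
  th <- theta_for(c(2, 0.5), 0.1, 0.2, diag(c(0.6, 0.25, 0.15)))
  set.seed(9)
  for (i in seq_along(m$env$persons)) {
    pp <- m$env$persons[[i]]
    ss <- emx("suffstats")(pp, th$beta)
    v <- rnorm(3, 0, 0.7)
    got <- emx("cond_ll_nodes")(pp, ss, th$s0, th$r0, matrix(v, 1))$ll
    sig2 <- exp(th$s0 + v[2]); rho <- tanh(th$r0 + v[3])
    want <- dense_mvn_logpdf(pp$y, drop(pp$X %*% th$beta) + v[1],
                             dense_ar1(sig2, rho, pp$T_len))
    expect_equal(got, want, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("single-occasion density and the quadratic form scale correctly", {
  # T = 1, v = 0, y at the mean: -0.5 log(2 pi sigma2/(1-rho^2))
  d <- data.frame(id = "a", time = 1, y = 2.5, x1 = 1)
  m <- toy_machine(y ~ 0 + x1, long_data(d, "y", "id", "time", "x1"))
  th <- theta_for(2.5, 0.3, 0.4, diag(3) * 0.2)
  pp <- m$env$persons[[1]]
  ss <- emx("suffstats")(pp, th$beta)
  got <- emx("cond_ll_nodes")(pp, ss, th$s0, th$r0, matrix(0, 1, 3))$ll
  c_stat <- exp(0.3) / (1 - tanh(0.4)^2)
  expect_equal(got, -0.5 * log(2 * pi * c_stat))

  # doubling the residual quadruples the Gaussian quadratic form
  sim <- toy_sim(I = 1, T_len = 6, seed = 6)
  m2 <- toy_machine(y ~ x1, sim)
  pp <- m2$env$persons[[1]]
  th2 <- theta_for(c(2, 0.5), 0, 0.2, diag(3) * 0.2)
  base_mu <- drop(pp$X %*% th2$beta)
  ll_at_scale <- function(k) {
    pp2 <- pp
    pp2$y <- base_mu + k * (pp$y - base_mu)
    ss <- emx("suffstats")(pp2, th2$beta)
    emx("cond_ll_nodes")(pp2, ss, th2$s0, th2$r0, matrix(0, 1, 3))$ll
  }
  const <- ll_at_scale(0)          # -logdet part only
  q1 <- 2 * (const - ll_at_scale(1))
  q2 <- 2 * (const - ll_at_scale(2))
  expect_equal(q2, 4 * q1, tolerance = 1e-10)
})

test_that("degenerate prior collapses the marginal onto v = 0", {
  sim <- toy_sim(I = 3, T_len = 5, seed = 7)
  m <- toy_machine(y ~ x1, sim, Q = 6)
  th <- theta_for(c(2, 0.5), 0.1, 0.2, diag(3) * 1e-12)
  rules <- emx("agh_adapt")(m$env, th)
  ll <- agh_ll(m, th, rules)$ll
  cond0 <- sum(vapply(m$env$persons, function(pp) {
    ss <- emx("suffstats")(pp, th$beta)
    emx("cond_ll_nodes")(pp, ss, th$s0, th$r0, matrix(0, 1, 3))$ll
  }, numeric(1)))
  expect_equal(ll, cond0, tolerance = 1e-4)
})

test_that("marginal likelihood is additive and stable under refinement", {
  sim <- toy_sim(I = 1, T_len = 5, seed = 8)
  d <- as.data.frame(sim)
  d2 <- rbind(d, transform(d, id = "p999"))
  ld2 <- long_data(d2, "y", "id", "time", "x1")
  th <- theta_for(c(2, 0.5), 0.1, 0.2, diag(c(0.6, 0.25, 0.15)))
  m1 <- toy_machine(y ~ x1, sim, Q = 10)
  m2 <- toy_machine(y ~ x1, ld2, Q = 10)
  expect_equal(agh_ll(m2, th)$ll, 2 * agh_ll(m1, th)$ll, tolerance = 1e-10)

  m20 <- toy_machine(y ~ x1, sim, Q = 20)
  expect_lt(abs(agh_ll(m1, th)$ll - agh_ll(m20, th)$ll), 1e-4)

  expect_error(toy_machine(y ~ x1, as.data.frame(sim)[0, ] |>
                             long_data("y", "id", "time", "x1")),
               "empty")
})

test_that("AGH value is invariant to person order and Phi factor", {
  sim <- toy_sim(I = 6, T_len = 5, seed = 9)
  d <- as.data.frame(sim)
  perm <- d[order(match(d$id, rev(unique(d$id))), d$time), ]
  ldp <- long_data(perm, "y", "id", "time", "x1")
  th <- theta_for(c(2, 0.5), 0.1, 0.2,
                  matrix(c(0.6, 0.1, 0.05, 0.1, 0.25, 0.02,
                           0.05, 0.02, 0.15), 3))
  m1 <- toy_machine(y ~ x1, sim, Q = 6)
  m2 <- toy_machine(y ~ x1, ldp, Q = 6)
  expect_equal(agh_ll(m1, th)$ll, agh_ll(m2, th)$ll, tolerance = 1e-6)
})

test_that("with zero location-scale variances the likelihood is the
           closed-form AR(1) mixed-model likelihood", {
  sim <- toy_sim(I = 8, T_len = 9, seed = 10)
  m <- toy_machine(y ~ x1, sim, Q = 8)
  beta <- c(2.1, 0.45); s0 <- 0.15; r0 <- 0.25; phi2 <- 0.5
  th <- theta_for(beta, s0, r0, diag(c(phi2, 1e-12, 1e-12)))
  ll_agh <- agh_ll(m, th)$ll
  # dense marginal-normal oracle: V = phi2 J + Sigma
  ll_dense <- sum(vapply(m$env$persons, function(pp) {
    V <- phi2 + dense_ar1(exp(s0), tanh(r0), pp$T_len)
    dense_mvn_logpdf(pp$y, drop(pp$X %*% beta), V)
  }, numeric(1)))
  expect_equal(ll_agh, ll_dense, tolerance = 1e-5, ignore_attr = TRUE)
  # and the package's own O(T) closed form agrees with the dense oracle
  ll_lmm <- emx("lmm_loglik")(m$env, c(beta, s0, r0, 0.5 * log(phi2)))
  expect_equal(ll_lmm, ll_dense, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("analytic score matches central finite differences", {
  sim <- toy_sim(I = 5, T_len = 6, seed = 11)
  m <- toy_machine(y ~ x1, sim, Q = 5)
  set.seed(12)
  for (rep in 1:3) {
    Phi <- crossprod(matrix(rnorm(9, 0, 0.4), 3)) + diag(3) * 0.3
    th <- theta_for(rnorm(2, c(2, 0.5), 0.2), rnorm(1, 0, 0.3),
                    rnorm(1, 0.2, 0.2), Phi)
    rules <- emx("agh_adapt")(m$env, th)
    g <- agh_ll(m, th, rules, want_grad = TRUE)$grad
    par <- emx("theta_pack")(th)
    fd <- emx("num_grad")(function(p)
      emx("agh_loglik")(m$env, emx("theta_unpack")(p, 2), m$grid,
                        rules)$ll, par)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1)), 1e-4)
  }
})

test_that("beta score reduces to the GLS score when the prior degenerates", {
  sim <- toy_sim(I = 4, T_len = 6, seed = 13)
  m <- toy_machine(y ~ x1, sim, Q = 8)
  beta <- c(1.8, 0.55); s0 <- 0.1; r0 <- 0.3
  th <- theta_for(beta, s0, r0, diag(3) * 1e-12)
  rules <- emx("agh_adapt")(m$env, th)
  g <- agh_ll(m, th, rules, want_grad = TRUE)$grad[1:2]
  gls <- Reduce(`+`, lapply(m$env$persons, function(pp) {
    S <- dense_ar1(exp(s0), tanh(r0), pp$T_len)
    drop(crossprod(pp$X, solve(S, pp$y - drop(pp$X %*% beta))))
  }))
  expect_equal(g, gls, tolerance = 1e-4, ignore_attr = TRUE)
})
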