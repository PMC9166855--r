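# The nested AR(1) linear mixed model: random intercept + stationary AR(1)
# residuals with common variance and autocorrelation (the location-scale
# random effects pinned at zero).  Its marginal likelihood is normal with
# V_i = phi2_tau J + Sigma, evaluated in O(T) per person via the Woodbury
# identity and the tridiagonal AR(1) inverse -- no quadrature needed.

lmm_par_pack <- function(beta, s0, r0, phi2_tau) {
  c(beta, s0, r0, 0.5 * log(phi2_tau))
}

lmm_loglik <- function(env, par) {
  nb <- env$n_beta
  beta <- par[seq_len(nb)]
  s0 <- par[nb + 1]; r0 <- par[nb + 2]; ltau <- par[nb + 3]
  sig2 <- exp(clip(s0, -EXP_CLIP, EXP_CLIP))
  a_rho <- clip(r0, -ATANH_CLIP, ATANH_CLIP)
  rho <- tanh(a_rho)
  log1mr2 <- -2 * (abs(a_rho) + log1p(exp(-2 * abs(a_rho))) - log(2))
  phi2 <- exp(clip(2 * ltau, -EXP_CLIP, EXP_CLIP))
  total <- 0
  for (pp in env$persons) {
    T_len <- pp$T_len
    r <- pp$y - drop(pp$X %*% beta)
    Br <- ar1_quad_apply(r, rho)
    B1 <- ar1_quad_apply(rep(1, T_len), rho)
    q <- sum(r * Br) / sig2
    h <- sum(B1) / sig2
    g <- sum(r * B1) / sig2
    logdetV <- T_len * log(sig2) - log1mr2 + log1p(phi2 * h)
    quad <- q - g^2 * phi2 / (1 + phi2 * h)
    total <- total - T_len / 2 * LOG2PI - 0.5 * logdetV - 0.5 * quad
  }
  unname(total)
}

# Closed-form empirical-Bayes intercepts: b_hat = Phi Z' V^{-1} (y - X beta),
# which for the random intercept reduces to phi2 g / (1 + phi2 h).
lmm_eb <- function(env, par) {
  nb <- env$n_beta
  beta <- par[seq_len(nb)]
  sig2 <- exp(par[nb + 1]); rho <- tanh(par[nb + 2])
  phi2 <- exp(2 * par[nb + 3])
  vapply(env$persons, function(pp) {
    r <- pp$y - drop(pp$X %*% beta)
    B1 <- ar1_quad_apply(rep(1, pp$T_len), rho)
    h <- sum(B1) / sig2
    g <- sum(r * B1) / sig2
    phi2 * g / (1 + phi2 * h)
  }, numeric(1))
}

# Core marginal-normal ML fit on a prepared series list; `par_init` is the
# packed (beta, s0, r0, log phi_tau) start (used for warm starts by the
# tree alternation).
lmm_fit_core <- function(series, par_init = NULL) {
  env <- emels_env(series)
  if (is.null(par_init)) {
    th0 <- init_theta(series)
    par_init <- c(th0$beta, th0$s0, th0$r0, 0.5 * log(0.1))
  }
  obj <- function(p) {
    v <- tryCatch(-lmm_loglik(env, p), error = function(e) NA_real_)
    if (!is.finite(v)) 1e12 else v
  }
  gr <- function(p) num_grad(obj, p)
  opt <- stats::nlminb(par_init, obj, gr,
                       control = list(iter.max = 500, rel.tol = 1e-12))
  par <- opt$par
  ll <- lmm_loglik(env, par)
  list(par = par, logLik = ll, env = env,
       converged = opt$convergence == 0 && is.finite(ll),
       iterations = opt$iterations,
       tau = lmm_eb(env, par))
}

#' Fit the AR(1) linear mixed model
#'
#' The special case of the location-scale model with the between-person
#' variances of the log residual variance and the atanh autocorrelation
#' fixed at zero: a random-intercept model with stationary AR(1) residuals
#' shared across persons.  Fitted by direct marginal-normal maximum
#' likelihood (no quadrature).
#'
#' @inheritParams emels
#' @return an object of class `emels` with `model = "lmm_ar1"`.
#' @seealso [emels()]; [anova.emels()] for the likelihood-ratio comparison.
#' @export
mem_ar1 <- function(formula = NULL, data, id = "id", time = "time", k = 1L,
                    se = TRUE, init = NULL, control = list()) {
  if (k != 1L)
    stop("only the random-intercept mean structure (k = 1) is supported")
  mi <- build_model_input(formula, data, id, time)
  par_init <- if (!is.null(init))
    c(init$beta, init$s0, init$r0, 0.5 * log(0.1)) else NULL
  core <- lmm_fit_core(mi$series, par_init)
  env <- core$env
  par <- core$par
  ll <- core$logLik
  converged <- core$converged
  nb <- env$n_beta
  beta <- stats::setNames(unname(par[seq_len(nb)]), mi$beta_names)
  s0 <- unname(par[nb + 1]); r0 <- unname(par[nb + 2])
  phi2_tau <- exp(2 * unname(par[nb + 3]))
  Phi <- diag(c(phi2_tau, 0, 0))
  dimnames(Phi) <- list(c("tau", "omega", "iota"), c("tau", "omega", "iota"))
  n_params <- nb + 3L
  vcov_un <- NULL; se_ok <- FALSE
  if (se) {
    H <- num_hessian(function(p) lmm_loglik(env, p), par)
    vcov_un <- tryCatch(solve(-(H + t(H)) / 2), error = function(e) NULL)
    if (!is.null(vcov_un) && all(is.finite(vcov_un)) &&
        all(diag(vcov_un) > 0)) se_ok <- TRUE else vcov_un <- NULL
  }
  tau_hat <- core$tau
  eb <- data.frame(id = vapply(env$persons, function(p) as.character(p$id), ""),
                   tau = tau_hat, omega = 0, iota = 0,
                   sigma2 = exp(s0), rho = tanh(r0),
                   stringsAsFactors = FALSE)
  theta <- theta_new(beta, s0, r0,
                     {lc <- numeric(6)
                      lc[match(which(diag(3) == 1), lower_tri_index(3))] <-
                        c(0.5 * log(max(phi2_tau, 1e-300)), -20, -20)
                      lc})
  fit <- structure(list(
    model = "lmm_ar1",
    theta = theta, beta = beta, Phi = Phi, s0 = s0, r0 = r0,
    logLik = ll, n_params = n_params, n_total = env$n_total,
    n_persons = env$n_persons,
    aic = -2 * ll + 2 * n_params,
    bic = -2 * ll + log(env$n_total) * n_params,
    converged = converged, n_iter = core$iterations,
    trace = ll, eb = eb, Q = NA_integer_,
    env = env, grid = NULL, rules = NULL,
    par_lmm = par,
    vcov_unconstrained = vcov_un, se_available = se_ok,
    terms = mi$terms, formula = mi$formula, ld = mi$ld,
    beta_names = mi$beta_names, call = match.call()), class = "emels")
  fit$report <- lmm_report_table(fit)
  fit
}

lmm_report_table <- function(fit) {
  nb <- length(fit$beta)
  est <- c(fit$beta,
           `intercept variance` = unname(fit$Phi[1, 1]),
           `residual variance (mean)` = exp(fit$s0),
           `autocorrelation (mean)` = tanh(fit$r0))
  ses <- rep(NA_real_, length(est))
  if (!is.null(fit$vcov_unconstrained)) {
    V <- fit$vcov_unconstrained
    ses[seq_len(nb)] <- sqrt(diag(V)[seq_len(nb)])
    ses[nb + 1] <- 2 * fit$Phi[1, 1] * sqrt(V[nb + 3, nb + 3])
    ses[nb + 2] <- exp(fit$s0) * sqrt(V[nb + 1, nb + 1])
    ses[nb + 3] <- (1 - tanh(fit$r0)^2) * sqrt(V[nb + 2, nb + 2])
  }
  data.frame(parameter = names(est), estimate = unname(est), se = ses,
             stringsAsFactors = FALSE)
}
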