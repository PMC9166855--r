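# Maximum-likelihood fitting of the extended mixed-effect location-scale
# model (random intercept + random log residual variance + random atanh
# autocorrelation) by adaptive Gauss-Hermite quadrature.

# Build the per-person design from a formula and a (long_data or plain)
# data.frame.  Returns the validated dataset, the model terms, and the
# series list consumed by the likelihood machinery.
build_model_input <- function(formula, data, id = NULL, time = NULL) {
  if (inherits(data, "long_data")) {
    idc <- attr(data, "id"); tmc <- attr(data, "time")
    if (missing(formula) || is.null(formula)) {
      preds <- attr(data, "predictors")
      formula <- stats::reformulate(if (length(preds)) preds else "1",
                                    response = attr(data, "outcome"))
    }
    ld <- data
  } else {
    if (is.null(id) || is.null(time))
      stop("supply `id` and `time` column names for a plain data.frame")
    vars <- all.vars(formula)
    outcome <- all.vars(formula[[2]])
    preds <- setdiff(intersect(vars, names(data)), c(outcome, id, time))
    ld <- long_data(data, outcome = outcome, id = id, time = time,
                    predictors = preds)
    idc <- id; tmc <- time
  }
  d <- as.data.frame(ld)
  mf <- stats::model.frame(formula, d)
  trms <- attr(mf, "terms")
  X <- stats::model.matrix(trms, mf)
  y <- stats::model.response(mf)
  ids <- d[[idc]]
  uid <- unique(ids)
  series <- lapply(uid, function(pid) {
    rows <- which(ids == pid)
    list(id = pid, y = y[rows], X = X[rows, , drop = FALSE],
         times = d[[tmc]][rows])
  })
  list(ld = ld, terms = trms, formula = formula, series = series,
       beta_names = colnames(X))
}

# Cheap consistent starting values: pooled OLS for beta, pooled residual
# variance for s0, pooled within-person lag-1 residual autocorrelation
# (clipped to |rho| <= 0.95) for r0, Phi = 0.1 * identity.
init_theta <- function(series, d = 3L) {
  Xall <- do.call(rbind, lapply(series, `[[`, "X"))
  yall <- unlist(lapply(series, `[[`, "y"))
  beta <- tryCatch(drop(qr.solve(qr(Xall), yall)),
                   error = function(e) {
                     b <- rep(0, ncol(Xall)); b[1] <- mean(yall); b
                   })
  num <- 0; den <- 0; rss <- 0
  for (ps in series) {
    r <- ps$y - drop(ps$X %*% beta)
    rss <- rss + sum(r^2)
    T_len <- length(r)
    if (T_len > 1) {
      num <- num + sum(r[-T_len] * r[-1])
      den <- den + sum(r^2)
    }
  }
  s0 <- log(max(rss / length(yall), 1e-4))
  rho0 <- if (den > 0) clip(num / den, -0.95, 0.95) else 0
  lchol <- numeric(d * (d + 1) / 2)
  Lidx <- lower_tri_index(d)
  diag_pos <- match(which(diag(d) == 1), Lidx)
  lchol[diag_pos] <- 0.5 * log(0.1)
  theta_new(stats::setNames(beta, colnames(Xall)), s0, atanh(rho0), lchol, d)
}

emels_control <- function(tol = 1e-6, max_cycles = 40L, inner_iter = 300L,
                          freeze_tol = 0.01, verbose = FALSE) {
  list(tol = tol, max_cycles = max_cycles, inner_iter = inner_iter,
       freeze_tol = freeze_tol, verbose = verbose)
}

# Core fitter on a prepared series list.  Alternates between refreshing the
# per-person quadrature adaptation and maximizing the fixed-rule AGH
# log-likelihood with a quasi-Newton step (analytic score).
emels_fit_core <- function(series, Q = 10L, init = NULL, control = list(),
                           d = 3L) {
  ctrl <- do.call(emels_control, control)
  env <- emels_env(series, d)
  grid <- gh_grid(Q, d)
  theta <- init %||% init_theta(series, d)
  rules <- agh_adapt(env, theta)
  par <- theta_pack(theta)
  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  n_cycles <- 0L
  # Once the per-person modes stop moving (max shift below freeze_tol) the
  # adaptation is frozen: the remaining cycles maximize one fixed smooth
  # surface, so the outer trace cannot oscillate around the joint fixed
  # point of (adapt, maximize).
  frozen <- FALSE
  for (cycle in seq_len(ctrl$max_cycles)) {
    n_cycles <- cycle
    obj <- function(p) {
      th <- theta_unpack(p, env$n_beta, d)
      v <- tryCatch(-agh_loglik(env, th, grid, rules)$ll +
                      lchol_barrier(th$lchol, d),
                    error = function(e) NA_real_)
      if (!is.finite(v)) 1e12 else v
    }
    gr <- function(p) {
      th <- theta_unpack(p, env$n_beta, d)
      g <- tryCatch({
        gg <- -agh_loglik(env, th, grid, rules, want_grad = TRUE)$grad
        nb <- env$n_beta
        gg[-seq_len(nb + 2)] <- gg[-seq_len(nb + 2)] +
          lchol_barrier_grad(th$lchol, d)
        gg
      }, error = function(e) rep(0, length(p)))
      g[!is.finite(g)] <- 0
      g
    }
    opt <- stats::nlminb(par, obj, gr,
                         control = list(iter.max = ctrl$inner_iter,
                                        rel.tol = 1e-9))
    par <- opt$par
    theta <- theta_unpack(par, env$n_beta, d)
    if (!frozen) {
      new_rules <- agh_adapt(env, theta, rules)
      shift <- max(vapply(seq_along(rules), function(i)
        max(abs(new_rules[[i]]$mode - rules[[i]]$mode)), numeric(1)))
      rules <- new_rules
      if (shift < ctrl$freeze_tol) frozen <- TRUE
    }
    ll <- agh_loglik(env, theta, grid, rules)$ll
    trace <- c(trace, ll)
    if (ctrl$verbose)
      message(sprintf("cycle %d: logL = %.6f", cycle, ll))
    if (is.finite(ll) && abs(ll - ll_prev) < ctrl$tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  theta$beta <- stats::setNames(theta$beta, colnames(env$persons[[1]]$X))
  eb <- agh_posterior_means(env, theta, grid, rules)
  list(theta = theta, logLik = trace[length(trace)], trace = trace,
       converged = converged, n_iter = n_cycles, eb = eb,
       env = env, grid = grid, rules = rules, Q = Q)
}

# Observed information (negative Hessian of the AGH log-likelihood at fixed
# final adaptation) by central differences of the analytic score.
emels_obs_info <- function(env, theta, grid, rules) {
  par <- theta_pack(theta)
  n <- length(par)
  gfun <- function(p)
    agh_loglik(env, theta_unpack(p, env$n_beta, env$d), grid, rules,
               want_grad = TRUE)$grad
  h <- 1e-5 * pmax(1, abs(par))
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    pp <- par; pp[j] <- pp[j] + h[j]
    pm <- par; pm[j] <- pm[j] - h[j]
    H[, j] <- (gfun(pp) - gfun(pm)) / (2 * h[j])
  }
  -(H + t(H)) / 2
}

#' Fit an extended mixed-effect location-scale model
#'
#' Fits the longitudinal random-intercept model whose residuals follow a
#' stationary AR(1) process with person-specific variance
#' \eqn{\exp(s_0 + \omega_i)} and autocorrelation \eqn{\tanh(r_0 + \iota_i)};
#' the random intercept \eqn{\tau_i} and the two location-scale deviations
#' \eqn{(\omega_i, \iota_i)} are jointly normal with free 3 x 3 covariance
#' \eqn{\Phi}.  The marginal likelihood integrates the three random effects
#' out by mode-adapted Gauss-Hermite quadrature (`Q` nodes per dimension) and
#' is maximized by a quasi-Newton method with the analytic score, on an
#' unconstrained parametrization (log-Cholesky for \eqn{\Phi}).
#'
#' @param formula model formula for the fixed-effect (mean) structure, e.g.
#'   `y ~ x1 + x2 + x1:x2`.  May be omitted when `data` is a [long_data()]
#'   object, in which case all recorded predictors enter linearly.
#' @param data a data.frame in long format or a [long_data()] object.
#' @param id,time column names of the person identifier and the occasion
#'   index (ignored for `long_data` input).
#' @param k number of mean-structure random effects; only the random
#'   intercept (`k = 1`) is supported.
#' @param Q quadrature nodes per dimension (default 10; 4-5 is usually
#'   enough for exploratory fits and is several times faster).
#' @param se compute standard errors from the observed information.
#' @param init optional starting parameter list (as produced by a previous
#'   fit's `$theta`).
#' @param control list of fitting controls: `tol` (relative log-likelihood
#'   change between adaptation cycles, default 1e-6), `max_cycles`,
#'   `inner_iter`, `verbose`.
#' @return an object of class `emels` with, among others, elements `beta`,
#'   `Phi`, `s0`, `r0`, `logLik`, `aic`, `bic`, `eb` (per-person
#'   empirical-Bayes effects), `report` (estimates and standard errors on
#'   the reporting scale) and `converged`.
#' @seealso [mem_ar1()] for the nested AR(1) linear mixed model,
#'   [emels_lasso()], [emels_tree()], [forecast.emels()].
#' @examples
#' sim <- simulate_emels_data(I = 25, T_len = 12, beta = c(2, 0.5),
#'                            s0 = 0, r0 = 0.2,
#'                            Phi = diag(c(0.8, 0.3, 0.2)), seed = 1)
#' fit <- emels(y ~ x1, sim, Q = 4, se = FALSE,
#'              control = list(max_cycles = 10))
#' coef(fit)
#' @export
emels <- function(formula = NULL, data, id = "id", time = "time", k = 1L,
                  Q = 10L, se = TRUE, init = NULL, control = list()) {
  if (k != 1L)
    stop("only the random-intercept mean structure (k = 1) is supported")
  mi <- build_model_input(formula, data, id, time)
  core <- emels_fit_core(mi$series, Q = Q, init = init, control = control)
  out <- finish_emels_fit(core, mi, model = "emels", se = se)
  out$call <- match.call()
  out
}

# Assemble the user-facing fit object shared by emels() and the tree fitter.
finish_emels_fit <- function(core, mi, model = "emels", se = TRUE) {
  theta <- core$theta
  env <- core$env
  Phi <- phi_from_lchol(theta$lchol, env$d)
  dimnames(Phi) <- list(c("tau", "omega", "iota"), c("tau", "omega", "iota"))
  n_params <- n_free_params(env$n_beta, env$d)
  vcov_un <- NULL
  se_ok <- FALSE
  if (se) {
    info <- emels_obs_info(env, theta, core$grid, core$rules)
    vcov_un <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(vcov_un) && all(is.finite(vcov_un)) &&
        all(diag(vcov_un) > 0)) se_ok <- TRUE else vcov_un <- NULL
  }
  eb <- as.data.frame(core$eb)
  eb$id <- rownames(core$eb)
  eb$sigma2 <- person_sigma2(theta$s0, eb$omega)
  eb$rho <- person_rho(theta$r0, eb$iota)
  rownames(eb) <- NULL
  fit <- structure(list(
    model = model,
    theta = theta,
    beta = theta$beta,
    Phi = Phi,
    s0 = theta$s0, r0 = theta$r0,
    logLik = core$logLik,
    n_params = n_params,
    n_total = env$n_total,
    n_persons = env$n_persons,
    aic = -2 * core$logLik + 2 * n_params,
    bic = -2 * core$logLik + log(env$n_total) * n_params,
    converged = core$converged,
    n_iter = core$n_iter,
    trace = core$trace,
    eb = eb[, c("id", "tau", "omega", "iota", "sigma2", "rho")],
    Q = core$Q,
    env = env, grid = core$grid, rules = core$rules,
    vcov_unconstrained = vcov_un,
    se_available = se_ok,
    terms = mi$terms, formula = mi$formula, ld = mi$ld,
    beta_names = mi$beta_names), class = "emels")
  fit$report <- report_table(fit)
  fit
}

# Parameter summary on the reporting scale: fixed effects as estimated, the
# residual-variance intercept as exp(s0), the autocorrelation intercept as
# tanh(r0), and the Phi variances; standard errors by the delta method from
# the unconstrained covariance.
report_table <- function(fit) {
  theta <- fit$theta
  nb <- length(theta$beta)
  d <- theta$d
  est <- c(theta$beta,
           `intercept variance` = unname(fit$Phi[1, 1]),
           `residual variance (mean)` = exp(theta$s0),
           `residual variance (between-person var)` = unname(fit$Phi[2, 2]),
           `autocorrelation (mean)` = tanh(theta$r0),
           `autocorrelation (between-person var)` = unname(fit$Phi[3, 3]))
  ses <- rep(NA_real_, length(est))
  if (!is.null(fit$vcov_unconstrained)) {
    V <- fit$vcov_unconstrained
    ses[seq_len(nb)] <- sqrt(diag(V)[seq_len(nb)])
    # delta method for the Phi variances through the log-Cholesky coords
    lidx <- nb + 2 + seq_len(d * (d + 1) / 2)
    Vl <- V[lidx, lidx, drop = FALSE]
    phi_entry <- function(lc, i) phi_from_lchol(lc, d)[i, i]
    for (j in 1:3) {
      Jg <- num_grad(function(lc) phi_entry(lc, j), theta$lchol)
      ses[nb + c(1, 3, 5)[j]] <- sqrt(max(drop(Jg %*% Vl %*% Jg), 0))
    }
    ses[nb + 2] <- exp(theta$s0) * sqrt(V[nb + 1, nb + 1])
    ses[nb + 4] <- (1 - tanh(theta$r0)^2) * sqrt(V[nb + 2, nb + 2])
  }
  data.frame(parameter = names(est), estimate = unname(est), se = ses,
             stringsAsFactors = FALSE)
}
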