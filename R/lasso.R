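# L1-penalized location-scale model: block coordinate descent alternating
# a proximal-gradient step with soft-thresholding for the fixed effects
# (slopes penalized, intercept free) and a quasi-Newton step for the
# variance/correlation block (s0, r0, Phi), both on the AGH log-likelihood
# with per-cycle refreshed adaptation.  The objective is
#   logL(theta) - lambda * sum_j |beta_j|   (j over the slopes).

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

lasso_control <- function(tol = 1e-6, max_cycles = 60L, beta_steps = 30L,
                          inner_iter = 100L, verbose = FALSE) {
  list(tol = tol, max_cycles = max_cycles, beta_steps = beta_steps,
       inner_iter = inner_iter, verbose = verbose)
}

# Core block-descent solver at a single penalty value.
emels_lasso_core <- function(series, lambda, Q = 10L, init = NULL,
                             control = list(), d = 3L) {
  stopifnot(lambda >= 0)
  ctrl <- do.call(lasso_control, control)
  env <- emels_env(series, d)
  grid <- gh_grid(Q, d)
  theta <- init %||% init_theta(series, d)
  nb <- env$n_beta
  pen_idx <- which(colnames(env$persons[[1]]$X) != "(Intercept)")
  rules <- agh_adapt(env, theta)
  penalty <- function(b) lambda * sum(abs(b[pen_idx]))
  ll_at <- function(th) agh_loglik(env, th, grid, rules)$ll
  pen_obj <- function(th) ll_at(th) - penalty(th$beta)

  t_step <- 0.5
  pen_trace <- numeric(0)
  pen_prev <- -Inf
  converged <- FALSE
  frozen <- FALSE
  stable_cycles <- 0L
  for (cycle in seq_len(ctrl$max_cycles)) {
    if (!frozen) {
      new_rules <- agh_adapt(env, theta, rules)
      shift <- max(vapply(seq_along(rules), function(i)
        max(abs(new_rules[[i]]$mode - rules[[i]]$mode)), numeric(1)))
      rules <- new_rules
      # freeze only once both the modes and the objective have stabilized;
      # the blocked updates move theta slowly, so mode stability alone can
      # occur far from the optimum
      if (cycle > 2 && shift < 0.01 && stable_cycles >= 2) frozen <- TRUE
    }
    # --- beta block: proximal gradient with backtracking ---
    for (s in seq_len(ctrl$beta_steps)) {
      ev <- agh_loglik(env, theta, grid, rules, want_grad = TRUE)
      g <- ev$grad[seq_len(nb)]
      pen0 <- ev$ll - penalty(theta$beta)
      accepted <- FALSE
      while (t_step > 1e-12) {
        cand <- theta$beta + t_step * g
        cand[pen_idx] <- soft_threshold(cand[pen_idx], t_step * lambda)
        th_c <- theta; th_c$beta <- cand
        pen_c <- tryCatch(ll_at(th_c) - penalty(cand),
                          error = function(e) -Inf)
        if (is.finite(pen_c) && pen_c >= pen0 - 1e-10) {
          theta <- th_c
          accepted <- TRUE
          break
        }
        t_step <- t_step / 2
      }
      if (!accepted) break
      pen_trace <- c(pen_trace, pen_c)
      if (pen_c - pen0 < 1e-9 * (abs(pen_c) + 1)) break
      t_step <- min(t_step * 1.8, 10)
    }
    # active-set polish: quasi-Newton over the nonzero coordinates, with
    # sign constraints on the penalized ones so the |.| kink is never
    # crossed (zero coordinates stay exactly zero).
    act <- which(theta$beta != 0 | !(seq_len(nb) %in% pen_idx))
    if (length(act)) {
      sgn <- sign(theta$beta)
      sgn[setdiff(seq_len(nb), pen_idx)] <- 0
      lower <- ifelse(sgn[act] > 0, 0, -Inf)
      upper <- ifelse(sgn[act] < 0, 0, Inf)
      bobj <- function(ba) {
        th <- theta; th$beta[act] <- ba
        v <- tryCatch(-(ll_at(th) - penalty(th$beta)),
                      error = function(e) NA_real_)
        if (!is.finite(v)) 1e12 else v
      }
      bgr <- function(ba) {
        th <- theta; th$beta[act] <- ba
        g <- tryCatch(-(agh_loglik(env, th, grid, rules,
                                   want_grad = TRUE)$grad[act] -
                          lambda * sgn[act]),
                      error = function(e) rep(0, length(ba)))
        g[!is.finite(g)] <- 0
        g
      }
      bopt <- stats::nlminb(theta$beta[act], bobj, bgr,
                            lower = lower, upper = upper,
                            control = list(iter.max = ctrl$inner_iter,
                                           rel.tol = 1e-10))
      pen_b <- -bopt$objective
      if (is.finite(pen_b) &&
          pen_b >= ll_at(theta) - penalty(theta$beta) - 1e-10) {
        theta$beta[act] <- bopt$par
        pen_trace <- c(pen_trace, pen_b)
      }
    }
    # --- gamma block: quasi-Newton on (s0, r0, lchol) at fixed beta ---
    gpar <- c(theta$s0, theta$r0, theta$lchol)
    gobj <- function(p) {
      th <- theta; th$s0 <- p[1]; th$r0 <- p[2]; th$lchol <- p[-(1:2)]
      v <- tryCatch(-ll_at(th) + lchol_barrier(th$lchol, d),
                    error = function(e) NA_real_)
      if (!is.finite(v)) 1e12 else v
    }
    ggr <- function(p) {
      th <- theta; th$s0 <- p[1]; th$r0 <- p[2]; th$lchol <- p[-(1:2)]
      g <- tryCatch({
        gg <- -agh_loglik(env, th, grid, rules,
                          want_grad = TRUE)$grad[-seq_len(nb)]
        gg[-(1:2)] <- gg[-(1:2)] + lchol_barrier_grad(th$lchol, d)
        gg
      }, error = function(e) rep(0, length(p)))
      g[!is.finite(g)] <- 0
      g
    }
    gopt <- stats::nlminb(gpar, gobj, ggr,
                          control = list(iter.max = ctrl$inner_iter,
                                         rel.tol = 1e-10))
    theta$s0 <- gopt$par[1]; theta$r0 <- gopt$par[2]
    theta$lchol <- gopt$par[-(1:2)]
    pen_cur <- pen_obj(theta)
    pen_trace <- c(pen_trace, pen_cur)
    if (ctrl$verbose)
      message(sprintf("lambda %.2f cycle %d: penalized logL = %.4f",
                      lambda, cycle, pen_cur))
    stable_cycles <- if (abs(pen_cur - pen_prev) <
                           1e-4 * (abs(pen_cur) + 1))
      stable_cycles + 1L else 0L
    if (abs(pen_cur - pen_prev) < ctrl$tol * (abs(pen_cur) + 1)) {
      if (frozen) {
        converged <- TRUE
        break
      }
      frozen <- TRUE   # objective stalled: pin the surface and finish on it
    }
    pen_prev <- pen_cur
  }
  # Final joint polish: with the support and signs fixed, the penalized
  # objective is smooth in (active beta, s0, r0, lchol) jointly, so a
  # sign-constrained quasi-Newton run escapes the slow zigzag of pure
  # block updates.  Zero coordinates stay exactly zero.
  for (round in 1:2) {
    rules <- agh_adapt(env, theta, rules)
    act <- which(theta$beta != 0 | !(seq_len(nb) %in% pen_idx))
    sgn <- sign(theta$beta)
    sgn[setdiff(seq_len(nb), pen_idx)] <- 0
    na <- length(act)
    p0 <- c(theta$beta[act], theta$s0, theta$r0, theta$lchol)
    # sign constraints on the penalized coordinates only matter when the
    # penalty is active; nlminb's unbounded path converges much better
    if (lambda > 0) {
      lower <- c(ifelse(sgn[act] > 0, 0, -Inf),
                 rep(-Inf, 2 + length(theta$lchol)))
      upper <- c(ifelse(sgn[act] < 0, 0, Inf),
                 rep(Inf, 2 + length(theta$lchol)))
    } else {
      lower <- rep(-Inf, length(p0)); upper <- rep(Inf, length(p0))
    }
    unpackj <- function(p) {
      th <- theta
      th$beta[act] <- p[seq_len(na)]
      th$s0 <- p[na + 1]; th$r0 <- p[na + 2]
      th$lchol <- p[-seq_len(na + 2)]
      th
    }
    jobj <- function(p) {
      th <- unpackj(p)
      v <- tryCatch(-(ll_at(th) - lambda * sum(sgn[act] * p[seq_len(na)])) +
                      lchol_barrier(th$lchol, d),
                    error = function(e) NA_real_)
      if (!is.finite(v)) 1e12 else v
    }
    jgr <- function(p) {
      g <- tryCatch({
        th <- unpackj(p)
        gfull <- agh_loglik(env, th, grid, rules, want_grad = TRUE)$grad
        gg <- -c(gfull[act] - lambda * sgn[act], gfull[-seq_len(nb)])
        gg[-seq_len(na + 2)] <- gg[-seq_len(na + 2)] +
          lchol_barrier_grad(th$lchol, d)
        gg
      }, error = function(e) rep(0, length(p)))
      g[!is.finite(g)] <- 0
      g
    }
    jopt <- stats::nlminb(p0, jobj, jgr, lower = lower, upper = upper,
                          control = list(iter.max = 300, rel.tol = 1e-10))
    cand <- unpackj(jopt$par)
    if (is.finite(jopt$objective) &&
        -jopt$objective >= pen_obj(theta) - 1e-8) {
      theta <- cand
      pen_trace <- c(pen_trace, -jopt$objective)
    }
  }
  ll_un <- ll_at(theta)
  theta$beta <- stats::setNames(theta$beta, colnames(env$persons[[1]]$X))
  list(theta = theta, logLik = ll_un,
       pen_logLik = ll_un - penalty(theta$beta),
       n_nonzero = sum(theta$beta != 0),
       converged = converged, pen_trace = pen_trace,
       env = env, grid = grid, rules = rules, Q = Q)
}

check_standardized <- function(env) {
  X <- do.call(rbind, lapply(env$persons, `[[`, "X"))
  slopes <- which(colnames(X) != "(Intercept)")
  if (!length(slopes)) return(invisible())
  sds <- apply(X[, slopes, drop = FALSE], 2, stats::sd)
  if (any(abs(sds - 1) > 0.25))
    warning("predictors do not look standardized (column SDs far from 1); ",
            "the L1 penalty is scale-sensitive", call. = FALSE)
}

#' L1-penalized location-scale model at a single penalty value
#'
#' @inheritParams emels
#' @param lambda non-negative L1 penalty on the slope coefficients (the
#'   intercept and all variance/correlation parameters are never
#'   penalized).
#' @param control list of controls: `tol`, `max_cycles`, `beta_steps`,
#'   `inner_iter`, `verbose`.
#' @return object of class `emels_lasso` with the sparse `beta` (exact
#'   zeros from the proximal map), the unpenalized and penalized
#'   log-likelihood at the solution, and the degrees of freedom
#'   `df = #nonzero beta + dim(Phi)`.
#' @export
emels_lasso <- function(formula = NULL, data, id = "id", time = "time",
                        lambda, Q = 10L, init = NULL, control = list()) {
  if (lambda < 0) stop("lambda must be non-negative")
  mi <- build_model_input(formula, data, id, time)
  core <- emels_lasso_core(mi$series, lambda, Q = Q, init = init,
                           control = control)
  check_standardized(core$env)
  df <- core$n_nonzero + 6L
  n <- core$env$n_total
  structure(list(
    lambda = lambda, theta = core$theta, beta = core$theta$beta,
    Phi = phi_from_lchol(core$theta$lchol, 3L),
    s0 = core$theta$s0, r0 = core$theta$r0,
    logLik = core$logLik, pen_logLik = core$pen_logLik,
    df = df,
    aic = -2 * core$logLik + 2 * df,
    bic = -2 * core$logLik + log(n) * df,
    n_nonzero = core$n_nonzero,
    converged = core$converged, pen_trace = core$pen_trace,
    env = core$env, grid = core$grid, rules = core$rules, Q = core$Q,
    terms = mi$terms, formula = mi$formula, ld = mi$ld,
    beta_names = mi$beta_names, call = match.call()),
    class = "emels_lasso")
}

#' @export
print.emels_lasso <- function(x, digits = 4, ...) {
  cat("L1-penalized location-scale model (lambda = ", x$lambda, ")\n",
      sep = "")
  cat("  nonzero fixed effects: ", x$n_nonzero, " of ", length(x$beta),
      "\n", sep = "")
  cat("  logLik: ", format(x$logLik, digits = digits + 3),
      "  penalized: ", format(x$pen_logLik, digits = digits + 3), "\n",
      sep = "")
  nz <- x$beta[x$beta != 0]
  print(round(nz, digits))
  invisible(x)
}

#' Penalty path with warm starts and information-criterion selection
#'
#' Fits the L1-penalized model over a grid of penalty values in increasing
#' order, warm-starting each fit from the previous solution, and selects
#' the penalty minimizing the chosen criterion
#' `-2 * logL + complexity * df` (the unpenalized log-likelihood at the
#' penalized estimate), with
#' `df = #nonzero beta + dim(Phi)` and `n = total observations`.
#'
#' @inheritParams emels_lasso
#' @param lambdas penalty grid (default 50 values linear on [0, 500]).
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return object of class `lasso_path`: a path table (lambda, logLik,
#'   df, AIC, BIC, n_nonzero), the per-lambda solutions, and the selected
#'   lambda for both criteria.
#' @export
lambda_path <- function(formula = NULL, data, id = "id", time = "time",
                        lambdas = seq(0, 500, length.out = 50),
                        criterion = c("bic", "aic"), Q = 10L,
                        control = list()) {
  criterion <- match.arg(criterion)
  if (!length(lambdas)) stop("empty lambda grid")
  if (any(lambdas < 0)) stop("lambda values must be non-negative")
  lambdas <- sort(lambdas)
  mi <- build_model_input(formula, data, id, time)
  fits <- vector("list", length(lambdas))
  init <- NULL
  rows <- vector("list", length(lambdas))
  n <- NULL
  for (j in seq_along(lambdas)) {
    core <- emels_lasso_core(mi$series, lambdas[j], Q = Q, init = init,
                             control = control)
    if (j == 1) check_standardized(core$env)
    init <- core$theta
    n <- core$env$n_total
    df <- core$n_nonzero + 6L
    rows[[j]] <- data.frame(
      lambda = lambdas[j], logLik = core$logLik,
      pen_logLik = core$pen_logLik, df = df,
      aic = -2 * core$logLik + 2 * df,
      bic = -2 * core$logLik + log(n) * df,
      n_nonzero = core$n_nonzero)
    fits[[j]] <- core$theta
  }
  tab <- do.call(rbind, rows)
  sel <- list(aic = tab$lambda[which.min(tab$aic)],
              bic = tab$lambda[which.min(tab$bic)])
  structure(list(table = tab, thetas = fits, lambdas = lambdas,
                 selected = sel, criterion = criterion,
                 terms = mi$terms, formula = mi$formula, ld = mi$ld,
                 beta_names = mi$beta_names, Q = Q,
                 call = match.call()),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat("L1 penalty path over", length(x$lambdas), "values in [",
      min(x$lambdas), ",", max(x$lambdas), "]\n")
  cat("  selected lambda: AIC ->", x$selected$aic,
      ", BIC ->", x$selected$bic, "\n")
  print(utils::head(x$table, 5))
  if (nrow(x$table) > 5) cat("  ... (", nrow(x$table), "rows )\n")
  invisible(x)
}

#' @export
plot.lasso_path <- function(x, ...) {
  tab <- x$table
  graphics::matplot(tab$lambda, cbind(tab$aic, tab$bic), type = "l",
                    lty = 1:2, xlab = expression(lambda),
                    ylab = "criterion", ...)
  graphics::legend("topleft", legend = c("AIC", "BIC"), lty = 1:2,
                   col = 1:2, bty = "n")
  graphics::abline(v = unlist(x$selected), lty = 3)
  invisible(x)
}

#' Unpenalized refit on the selected support
#'
#' Refits the plain location-scale model using only the predictors with
#' nonzero coefficients at the selected penalty (the intercept is always
#' kept; an empty support gives an intercept-only location-scale model).
#' The refit feeds all downstream forecasting.
#'
#' @param path a `lasso_path` object.
#' @param criterion `"bic"` or `"aic"` (defaults to the path's criterion).
#' @param Q quadrature nodes per dimension for the refit.
#' @param se,control passed to the refit.
#' @return an `emels` fit restricted to the selected columns.
#' @export
refit_selected <- function(path, criterion = NULL, Q = NULL,
                           se = TRUE, control = list()) {
  stopifnot(inherits(path, "lasso_path"))
  criterion <- criterion %||% path$criterion
  lam <- path$selected[[criterion]]
  j <- which(path$lambdas == lam)[1]
  beta <- path$thetas[[j]]$beta
  keep <- which(beta != 0 | names(beta) == "(Intercept)")
  mi <- list(ld = path$ld, terms = path$terms, formula = path$formula,
             beta_names = path$beta_names[keep])
  series <- build_model_input(path$formula, path$ld)$series
  series <- lapply(series, function(s) {
    s$X <- s$X[, keep, drop = FALSE]; s
  })
  core <- emels_fit_core(series, Q = Q %||% path$Q, control = control)
  fit <- finish_emels_fit(core, mi, model = "emels", se = se)
  fit$x_cols <- keep
  fit$selected_lambda <- lam
  fit$call <- match.call()
  fit
}
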