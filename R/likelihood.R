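# Marginal likelihood of the location-scale model by adaptive Gauss-Hermite
# quadrature.
#
# For person i with random effects v = (b, omega, iota):
#   y_i | v ~ N(X_i beta + b,  Sigma_i(exp(s0 + omega), tanh(r0 + iota)))
#   v ~ N(0, Phi)
# and the person's marginal likelihood is the 3-d integral of the product.
# The conditional density only touches the data through five scalar sums of
# the fixed-effect residual r = y - X beta (plus their X-weighted versions
# for the score), so a whole block of quadrature nodes is evaluated with a
# handful of vectorized operations per person.
#
# Quadrature nodes are recentred and rescaled per person at the posterior
# mode of v with the curvature there (standard mode-adapted AGH); the
# adaptation is refreshed between outer optimization cycles, so within one
# cycle the nodes are fixed and the analytic score below is the exact
# gradient of the approximated log-likelihood (Fisher's identity over the
# normalized node weights).

LOG2PI <- log(2 * pi)
ATANH_CLIP <- 18  # tanh argument clip; tanh(18) is 1 within double precision

# --- node grid ---------------------------------------------------------------

# Product Gauss-Hermite grid over d dimensions: node matrix (Q^d x d),
# summed log-weights and squared node norms (both length Q^d).
gh_grid <- function(Q, d = 3L) {
  gh <- gauss_hermite(Q)
  idx <- do.call(expand.grid, rep(list(seq_len(Q)), d))
  Xq <- matrix(gh$nodes[as.matrix(idx)], nrow(idx), d)
  lw <- rowSums(matrix(log(gh$weights)[as.matrix(idx)], nrow(idx), d))
  list(Q = Q, d = d, Xq = Xq, lw = lw, x2 = rowSums(Xq^2))
}

# --- per-person precomputation ----------------------------------------------

# Static per-person pieces (independent of theta): design, outcome, and the
# column sums needed for the score.
prep_series <- function(series) {
  lapply(series, function(ps) {
    X <- as.matrix(ps$X)
    y <- as.numeric(ps$y)
    T_len <- length(y)
    stopifnot(nrow(X) == T_len, T_len >= 1)
    mid <- if (T_len > 2) 2:(T_len - 1) else integer(0)
    list(id = ps$id, y = y, X = X, T_len = T_len, mid = mid,
         times = ps$times %||% seq_len(T_len),
         cs0 = colSums(X),
         csm = if (length(mid)) colSums(X[mid, , drop = FALSE])
               else numeric(ncol(X)),
         cs1 = if (T_len > 1)
                 colSums(X[-T_len, , drop = FALSE]) +
                 colSums(X[-1, , drop = FALSE])
               else numeric(ncol(X)))
  })
}

emels_env <- function(series, d = 3L) {
  if (!length(series)) stop("empty dataset: no person series")
  persons <- prep_series(series)
  list(persons = persons,
       n_beta = ncol(persons[[1]]$X),
       n_persons = length(persons),
       n_total = sum(vapply(persons, `[[`, 0, "T_len")),
       d = d)
}

# beta-dependent sufficient statistics of the residual r = y - X beta.
suffstats <- function(pp, beta, want_grad = FALSE) {
  r <- pp$y - drop(pp$X %*% beta)
  T_len <- pp$T_len
  ss <- list(
    q0 = sum(r * r), l0 = sum(r),
    qm = 0, lm = 0, q1 = 0, l1 = 0)
  if (length(pp$mid)) {
    rm_ <- r[pp$mid]
    ss$qm <- sum(rm_ * rm_); ss$lm <- sum(rm_)
  }
  if (T_len > 1) {
    ss$q1 <- sum(r[-T_len] * r[-1])
    ss$l1 <- sum(r[-T_len]) + sum(r[-1])
  }
  if (want_grad) {
    ss$u0 <- drop(crossprod(pp$X, r))
    ss$um <- if (length(pp$mid))
      drop(crossprod(pp$X[pp$mid, , drop = FALSE], r[pp$mid]))
      else numeric(ncol(pp$X))
    ss$u1 <- if (T_len > 1)
      drop(crossprod(pp$X[-T_len, , drop = FALSE], r[-1])) +
      drop(crossprod(pp$X[-1, , drop = FALSE], r[-T_len]))
      else numeric(ncol(pp$X))
  }
  ss
}

# --- conditional and joint log-densities over node blocks ---------------------

# Conditional log-density of y_i given random effects, evaluated at each row
# of V (columns b, omega, iota).  Returns the per-node pieces needed by the
# score when `want_parts`.
cond_ll_nodes <- function(pp, ss, s0, r0, V, want_parts = FALSE) {
  T_len <- pp$T_len
  b <- V[, 1]
  a_sig <- clip(s0 + V[, 2], -EXP_CLIP, EXP_CLIP)
  a_rho <- clip(r0 + V[, 3], -ATANH_CLIP, ATANH_CLIP)
  sig2 <- exp(a_sig)
  rho <- tanh(a_rho)
  log1mr2 <- -2 * (abs(a_rho) + log1p(exp(-2 * abs(a_rho))) - log(2))
  Q0 <- ss$q0 - 2 * b * ss$l0 + T_len * b^2
  if (T_len == 1L) {
    q <- exp(log1mr2) * Q0 / sig2
    Qm <- Q1 <- rep(0, length(b))
  } else {
    Qm <- ss$qm - 2 * b * ss$lm + max(T_len - 2L, 0L) * b^2
    Q1 <- ss$q1 - b * ss$l1 + (T_len - 1L) * b^2
    q <- (Q0 + rho^2 * Qm - 2 * rho * Q1) / sig2
  }
  ll <- -T_len / 2 * LOG2PI - 0.5 * (T_len * a_sig - log1mr2) - q / 2
  if (!want_parts) return(list(ll = ll))
  list(ll = ll, b = b, sig2 = sig2, rho = rho, q = q,
       Q0 = Q0, Qm = Qm, Q1 = Q1, log1mr2 = log1mr2)
}

# All prior computations run in the whitened frame u = L^{-1} v (L the
# lower Cholesky factor of Phi): quadratic forms, densities and the
# Phi-score stay numerically stable even when Phi is nearly singular,
# where forming Phi^{-1} explicitly loses all precision to cancellation.
prior_prep <- function(Phi) {
  ch <- tryCatch(chol(Phi), error = function(e) NULL)
  if (is.null(ch)) stop("random-effect covariance is not positive definite")
  prior_from_L(t(ch))
}

# Build the prior directly from the log-Cholesky parameter vector: the
# factor is the parameter, so no round trip through Phi (which would lose
# the tiny diagonal entries of a near-singular factor to cancellation).
prior_prep_lchol <- function(lchol, d = 3L) {
  prior_from_L(lchol_to_L(lchol, d))
}

prior_from_L <- function(L) {
  Linv <- forwardsolve(L, diag(nrow(L)))
  list(Phi = tcrossprod(L), L = L, Linv = Linv, tLinv = t(Linv),
       logdet = 2 * sum(log(diag(L))))
}

prior_ll_nodes <- function(V, prior, d = 3L) {
  U <- V %*% prior$tLinv
  -d / 2 * LOG2PI - 0.5 * prior$logdet - 0.5 * rowSums(U * U)
}

# Joint log f(y, v) at a single point v (used by the mode finder).
joint_ll_point <- function(v, pp, ss, s0, r0, prior) {
  V <- matrix(v, 1L)
  cond_ll_nodes(pp, ss, s0, r0, V)$ll + prior_ll_nodes(V, prior)
}

# Analytic gradient of the joint log-density with respect to v.
joint_grad_point <- function(v, pp, ss, s0, r0, prior) {
  V <- matrix(v, 1L)
  parts <- cond_ll_nodes(pp, ss, s0, r0, V, want_parts = TRUE)
  T_len <- pp$T_len
  b <- parts$b; sig2 <- parts$sig2; rho <- parts$rho
  dQ0 <- -2 * ss$l0 + 2 * T_len * b
  if (T_len == 1L) {
    g_b <- -(1 - rho^2) * dQ0 / (2 * sig2)
    g_iota <- -rho + (1 - rho^2) * rho * parts$Q0 / sig2
  } else {
    dQm <- -2 * ss$lm + 2 * max(T_len - 2L, 0L) * b
    dQ1 <- -ss$l1 + 2 * (T_len - 1L) * b
    g_b <- -(dQ0 + rho^2 * dQm - 2 * rho * dQ1) / (2 * sig2)
    g_iota <- -rho + (1 - rho^2) * (parts$Q1 - rho * parts$Qm) / sig2
  }
  g_omega <- -T_len / 2 + parts$q / 2
  drop(c(g_b, g_omega, g_iota) -
         prior$tLinv %*% (prior$Linv %*% v))
}

# --- adaptation ---------------------------------------------------------------

# Posterior mode and curvature of v for one person; returns the node shift
# (mode), a factor L with L L' = H^{-1} (H = negative Hessian at the mode),
# and log|det L|.
adapt_person <- function(pp, ss, s0, r0, prior, start = rep(0, 3)) {
  negf <- function(v) -joint_ll_point(v, pp, ss, s0, r0, prior)
  negg <- function(v) -joint_grad_point(v, pp, ss, s0, r0, prior)
  opt <- stats::optim(start, negf, negg, method = "BFGS",
                      control = list(maxit = 100, reltol = 1e-12))
  mode <- opt$par
  # curvature: central differences of the analytic gradient
  h <- 1e-4
  H <- matrix(0, 3, 3)
  for (j in 1:3) {
    vp <- mode; vp[j] <- vp[j] + h
    vm <- mode; vm[j] <- vm[j] - h
    H[, j] <- (negg(vp) - negg(vm)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) {
    H <- H + diag(3) * (abs(min(eigen(H, symmetric = TRUE,
                                      only.values = TRUE)$values)) + 1e-4)
    R <- chol(H)
  }
  L <- backsolve(R, diag(3))           # L = R^{-1}, L L' = H^{-1}
  list(mode = mode, L = L, logdetL = -sum(log(diag(R))))
}

agh_adapt <- function(env, theta, modes = NULL) {
  prior <- prior_prep_lchol(theta$lchol, env$d)
  lapply(seq_along(env$persons), function(i) {
    pp <- env$persons[[i]]
    ss <- suffstats(pp, theta$beta)
    start <- if (is.null(modes)) rep(0, env$d) else modes[[i]]$mode
    adapt_person(pp, ss, theta$s0, theta$r0, prior, start = start)
  })
}

# --- marginal log-likelihood and score ----------------------------------------

person_nodes <- function(rule, grid) {
  V <- grid$Xq %*% (sqrt(2) * t(rule$L))
  V[, 1] <- V[, 1] + rule$mode[1]
  V[, 2] <- V[, 2] + rule$mode[2]
  V[, 3] <- V[, 3] + rule$mode[3]
  V
}

# AGH marginal log-likelihood of one person (optionally with the pieces the
# score and the empirical-Bayes posterior mean need).
person_marginal <- function(pp, ss, theta, prior, rule, grid,
                            want_grad = FALSE) {
  V <- person_nodes(rule, grid)
  parts <- cond_ll_nodes(pp, ss, theta$s0, theta$r0, V,
                         want_parts = want_grad)
  lt <- grid$lw + grid$x2 + parts$ll + prior_ll_nodes(V, prior, env_d(grid))
  m <- max(lt)
  if (!is.finite(m))
    stop("non-finite integrand for person '", pp$id, "'")
  w <- exp(lt - m)
  S <- sum(w)
  ll <- grid$d / 2 * log(2) + rule$logdetL + m + log(S)
  if (!want_grad) return(list(ll = ll))
  list(ll = ll, V = V, wt = w / S, parts = parts)
}

env_d <- function(grid) grid$d

# Total AGH log-likelihood (and score over the packed parameter vector) at
# fixed adaptation rules.
agh_loglik <- function(env, theta, grid, rules, want_grad = FALSE) {
  prior <- prior_prep_lchol(theta$lchol, env$d)
  d <- env$d
  total <- 0
  if (want_grad) {
    g_beta <- numeric(env$n_beta)
    g_s0 <- 0; g_r0 <- 0
    Sm <- matrix(0, d, d)
  }
  for (i in seq_along(env$persons)) {
    pp <- env$persons[[i]]
    ss <- suffstats(pp, theta$beta, want_grad = want_grad)
    pm <- person_marginal(pp, ss, theta, prior, rules[[i]], grid,
                          want_grad = want_grad)
    total <- total + pm$ll
    if (want_grad) {
      wt <- pm$wt; parts <- pm$parts
      T_len <- pp$T_len
      b <- parts$b; sig2 <- parts$sig2; rho <- parts$rho
      if (T_len == 1L) {
        f <- (1 - rho^2) / sig2
        g_beta <- g_beta + ss$u0 * sum(wt * f) - pp$cs0 * sum(wt * f * b)
        g_r0 <- g_r0 + sum(wt * (-rho + (1 - rho^2) * rho * parts$Q0 / sig2))
      } else {
        a1 <- sum(wt / sig2);        a2 <- sum(wt * b / sig2)
        a3 <- sum(wt * rho^2 / sig2); a4 <- sum(wt * rho^2 * b / sig2)
        a5 <- sum(wt * rho / sig2);   a6 <- sum(wt * rho * b / sig2)
        g_beta <- g_beta + ss$u0 * a1 - pp$cs0 * a2 +
          ss$um * a3 - pp$csm * a4 - ss$u1 * a5 + pp$cs1 * a6
        g_r0 <- g_r0 + sum(wt * (-rho + (1 - rho^2) *
                                   (parts$Q1 - rho * parts$Qm) / sig2))
      }
      g_s0 <- g_s0 + sum(wt * (-T_len / 2 + parts$q / 2))
      Vu <- pm$V %*% prior$tLinv
      Sm <- Sm + crossprod(Vu, wt * Vu)
    }
  }
  if (!want_grad) return(list(ll = total))
  # Phi block in the whitened frame: with U = sum_i E[u_i u_i'] the score
  # with respect to the Cholesky factor is L^{-T} (U - n I), whose diagonal
  # is rescaled for the log-diagonal parametrization.
  G_L <- prior$tLinv %*% (Sm - env$n_persons * diag(d))
  diag(G_L) <- diag(G_L) * diag(prior$L)
  g_lchol <- G_L[lower_tri_index(d)]
  list(ll = total, grad = c(g_beta, g_s0, g_r0, g_lchol))
}

# Empirical-Bayes posterior means E[v | y] per person at fixed adaptation.
agh_posterior_means <- function(env, theta, grid, rules) {
  prior <- prior_prep_lchol(theta$lchol, env$d)
  out <- matrix(0, env$n_persons, env$d)
  for (i in seq_along(env$persons)) {
    pp <- env$persons[[i]]
    ss <- suffstats(pp, theta$beta)
    pm <- person_marginal(pp, ss, theta, prior, rules[[i]], grid,
                          want_grad = TRUE)
    out[i, ] <- colSums(pm$wt * pm$V)
  }
  rownames(out) <- vapply(env$persons, function(p) as.character(p$id), "")
  colnames(out) <- c("tau", "omega", "iota")[seq_len(env$d)]
  out
}
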