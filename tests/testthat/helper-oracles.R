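# Shared fixtures and independent oracles used across the suite.
# Oracles here deliberately use dense linear algebra / brute force, never the
# package's O(T) or quadrature code paths.

# Dense AR(1) covariance, written independently of ar1_covariance().
dense_ar1 <- function(sigma2, rho, T_len) {
  M <- matrix(0, T_len, T_len)
  for (j in seq_len(T_len))
    for (k in seq_len(T_len))
      M[j, k] <- sigma2 / (1 - rho^2) * rho^abs(j - k)
  M
}

# Dense multivariate normal log-density.
dense_mvn_logpdf <- function(x, mu, S) {
  e <- x - mu
  -0.5 * (length(x) * log(2 * pi) + determinant(S)$modulus[1] +
            drop(e %*% solve(S, e)))
}

# A small linear location-scale simulation used by several files.
toy_sim <- function(I = 12, T_len = 8, seed = 1,
                    beta = c(2, 0.5), s0 = 0.1, r0 = 0.2,
                    Phi = diag(c(0.6, 0.25, 0.15))) {
  simulate_emels_data(I = I, T_len = T_len, beta = beta, s0 = s0, r0 = r0,
                      Phi = Phi, seed = seed)
}

# Internal handles (the suite runs against the installed namespace).
emx <- function(name) get(name, envir = asNamespace("emels"))

# Build the likelihood machinery for a formula + dataset.
toy_machine <- function(formula, data, Q = 6) {
  mi <- emx("build_model_input")(formula, data)
  env <- emx("emels_env")(mi$series)
  grid <- emx("gh_grid")(Q)
  list(mi = mi, env = env, grid = grid)
}

theta_for <- function(beta, s0, r0, Phi) {
  emx("theta_new")(beta, s0, r0, emx("lchol_from_phi")(Phi))
}

agh_ll <- function(m, th, rules = NULL, want_grad = FALSE) {
  if (is.null(rules)) rules <- emx("agh_adapt")(m$env, th)
  emx("agh_loglik")(m$env, th, m$grid, rules, want_grad = want_grad)
}

# Brute-force best single split over all variables and all midpoints of
# consecutive sorted unique values: returns the minimal total SSE.
brute_best_split <- function(x, y, minbucket = 1) {
  best <- Inf
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  for (j in seq_along(x)) {
    xs <- sort(unique(x[[j]]))
    if (length(xs) < 2) next
    cuts <- (xs[-1] + xs[-length(xs)]) / 2
    for (s in cuts) {
      L <- y[x[[j]] < s]; R <- y[x[[j]] >= s]
      if (length(L) < minbucket || length(R) < minbucket) next
      val <- sse(L) + sse(R)
      if (val < best) best <- val
    }
  }
  best
}
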