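# Parameter vector layout and the log-Cholesky parametrization of Phi.
#
# The full parameter list is
#   beta  : fixed effects (length n_beta, including an intercept or the
#           leaf-dummy means of a tree fit),
#   s0    : mean log residual variance,
#   r0    : mean atanh lag-1 autocorrelation,
#   lchol : lower-triangular Cholesky factor of the random-effect covariance
#           Phi (d x d, d = k + 2), column-major, with the diagonal stored on
#           the log scale so the packed vector is unconstrained.

theta_new <- function(beta, s0, r0, lchol, d = 3L) {
  list(beta = beta, s0 = s0, r0 = r0, lchol = lchol, d = d)
}

theta_pack <- function(theta) {
  c(theta$beta, theta$s0, theta$r0, theta$lchol)
}

theta_unpack <- function(par, n_beta, d = 3L) {
  nl <- d * (d + 1) / 2
  list(beta = unname(par[seq_len(n_beta)]),
       s0 = unname(par[n_beta + 1]),
       r0 = unname(par[n_beta + 2]),
       lchol = unname(par[n_beta + 2 + seq_len(nl)]),
       d = d)
}

lower_tri_index <- function(d) which(lower.tri(diag(d), diag = TRUE))

lchol_to_L <- function(lchol, d) {
  L <- matrix(0, d, d)
  L[lower_tri_index(d)] <- lchol
  diag(L) <- exp(clip(diag(L), -EXP_CLIP, EXP_CLIP))
  L
}

phi_from_lchol <- function(lchol, d = 3L) {
  L <- lchol_to_L(lchol, d)
  tcrossprod(L)
}

lchol_from_phi <- function(Phi) {
  d <- nrow(Phi)
  L <- t(chol(Phi))
  diag(L) <- log(diag(L))
  L[lower_tri_index(d)]
}

# Number of free parameters of the unpenalized model: fixed effects + the
# two location-scale intercepts + the free entries of Phi.
n_free_params <- function(n_beta, d = 3L) n_beta + 2L + d * (d + 1L) / 2L

lchol_diag_pos <- function(d = 3L) match(which(diag(d) == 1), lower_tri_index(d))

# Smooth barrier keeping the log-Cholesky diagonals above -6 (a conditional
# SD floor of exp(-6) ~ 2.5e-3, zero for practical purposes).  A collapsing
# factor creates a razor-thin valley (curvature ~ 1/L_jj^2) that finite
# quasi-Newton steps cannot traverse; the quadratic barrier switches on only
# below the floor, so the likelihood is untouched wherever the variances are
# scientifically meaningful.  (Box bounds are not used: nlminb's bounded
# algorithm converges far more slowly even when no bound is active.)
LCHOL_BARRIER_AT <- -6
LCHOL_BARRIER_W <- 100

lchol_barrier <- function(lchol, d = 3L) {
  v <- pmin(lchol[lchol_diag_pos(d)] - LCHOL_BARRIER_AT, 0)
  LCHOL_BARRIER_W * sum(v * v)
}

# gradient over the lchol coordinates only
lchol_barrier_grad <- function(lchol, d = 3L) {
  g <- numeric(length(lchol))
  pos <- lchol_diag_pos(d)
  g[pos] <- 2 * LCHOL_BARRIER_W * pmin(lchol[pos] - LCHOL_BARRIER_AT, 0)
  g
}
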