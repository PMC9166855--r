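# Person-specific AR(1) residual covariance and the location-scale links.
#
# The residual vector of person i is stationary AR(1) with variance
# sigma2_i / (1 - rho_i^2) on the diagonal and lag-h correlation rho_i^h,
# where sigma2_i = exp(s0 + omega_i) and rho_i = tanh(r0 + iota_i).
# The inverse of the lag correlation matrix is tridiagonal, which gives the
# O(T) log-determinant and solve used throughout the likelihood.

# exponent clip: quadrature tail nodes in the 3-d rule can push s0 + omega
# to values whose exp over/underflows; [-30, 30] keeps exp() finite without
# affecting any realistic parameter region.
EXP_CLIP <- 30

#' Person-specific residual variance
#'
#' `exp(s0 + omega)`: the log-linear link mapping the mean log residual
#' variance and a person's deviation to that person's residual variance.
#'
#' @param s0 mean of the log residual variance.
#' @param omega person-specific deviation (0 for the average person).
#' @return strictly positive variance.
#' @export
person_sigma2 <- function(s0, omega = 0) {
  exp(clip(s0 + omega, -EXP_CLIP, EXP_CLIP))
}

#' Person-specific autocorrelation
#'
#' `tanh(r0 + iota)`: maps the mean atanh autocorrelation and a person's
#' deviation to that person's lag-1 autocorrelation in (-1, 1).
#'
#' @param r0 mean of the atanh autocorrelation.
#' @param iota person-specific deviation (0 for the average person).
#' @return autocorrelation strictly inside (-1, 1).
#' @export
person_rho <- function(r0, iota = 0) tanh(r0 + iota)

#' Stationary AR(1) residual covariance matrix
#'
#' Entry (j, k) is `sigma2 / (1 - rho^2) * rho^|j - k|`: the stationary
#' variance on the diagonal, geometric decay off it.
#'
#' @param sigma2 innovation variance (> 0).
#' @param rho lag-1 autocorrelation, |rho| < 1.
#' @param T_len series length (>= 1).
#' @return a `T_len` x `T_len` symmetric positive definite matrix.
#' @export
ar1_covariance <- function(sigma2, rho, T_len) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  stopifnot(T_len >= 1)
  idx <- seq_len(T_len)
  sigma2 / (1 - rho^2) * rho^abs(outer(idx, idx, "-"))
}

#' Log-determinant and linear solve for the AR(1) covariance
#'
#' Computes `log det Sigma` and `Sigma^{-1} %*% rhs` in O(T) per column via
#' the tridiagonal inverse of the AR(1) correlation matrix, avoiding any
#' dense factorization.
#'
#' @inheritParams ar1_covariance
#' @param rhs numeric vector or matrix with `T_len` rows.
#' @return list with `logdet` (scalar) and `solve` (same shape as `rhs`).
#' @export
ar1_logdet_solve <- function(sigma2, rho, T_len, rhs) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  rhs <- as.matrix(rhs)
  stopifnot(nrow(rhs) == T_len)
  # log det: T * log(sigma2/(1-rho^2)) + (T-1) * log(1-rho^2)
  logdet <- T_len * log(sigma2) - log(1 - rho^2)
  sol <- ar1_quad_apply(rhs, rho) / sigma2
  list(logdet = logdet, solve = sol)
}

# Apply B = sigma2 * Sigma^{-1} (the scaled tridiagonal inverse) to a
# vector/matrix.  For T = 1, B = 1 - rho^2.
ar1_quad_apply <- function(e, rho) {
  e <- as.matrix(e)
  T_len <- nrow(e)
  if (T_len == 1L) return((1 - rho^2) * e)
  out <- e
  mid <- seq_len(T_len)[-c(1L, T_len)]
  if (length(mid)) out[mid, ] <- out[mid, ] + rho^2 * e[mid, , drop = FALSE]
  out[-T_len, ] <- out[-T_len, , drop = FALSE] - rho * e[-1L, , drop = FALSE]
  out[-1L, ] <- out[-1L, , drop = FALSE] - rho * e[-T_len, , drop = FALSE]
  out
}

# Quadratic form e' Sigma^{-1} e in O(T) given the scalar sufficient sums.
# q0 = sum e^2, qm = sum over interior e^2, q1 = sum e_t e_{t+1}.
ar1_quadform <- function(q0, qm, q1, sigma2, rho, T_len) {
  if (T_len == 1L) return((1 - rho^2) * q0 / sigma2)
  (q0 + rho^2 * qm - 2 * rho * q1) / sigma2
}
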