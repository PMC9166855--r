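# Seed-deterministic generators emitting data with the exact structure the
# models assume: normal random effects (tau, omega, iota) with covariance
# Phi, and stationary person-specific AR(1) residuals.

# One stationary AR(1) draw: e_1 ~ N(0, sigma2/(1-rho^2)),
# e_t = rho e_{t-1} + N(0, sigma2).
sim_ar1_vector <- function(T_len, sigma2, rho) {
  e <- numeric(T_len)
  e[1] <- stats::rnorm(1, 0, sqrt(sigma2 / (1 - rho^2)))
  if (T_len > 1) {
    innov <- stats::rnorm(T_len - 1, 0, sqrt(sigma2))
    for (t in 2:T_len) e[t] <- rho * e[t - 1] + innov[t - 1]
  }
  e
}

#' Simulate a stationary AR(1) error series
#'
#' @param T_len series length.
#' @param sigma2 innovation variance (> 0); the stationary variance is
#'   `sigma2 / (1 - rho^2)`.
#' @param rho lag-1 autocorrelation, |rho| < 1.
#' @param seed optional RNG seed for a reproducible draw.
#' @return numeric vector of length `T_len`.
#' @export
simulate_ar1_errors <- function(T_len, sigma2, rho, seed = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  stopifnot(T_len >= 1)
  if (!is.null(seed)) set.seed(seed)
  sim_ar1_vector(T_len, sigma2, rho)
}

#' Simulate data from a linear location-scale model
#'
#' Draws `I` persons with `T_len` occasions each: per-person random effects
#' `v_i = (tau_i, omega_i, iota_i) ~ N(0, Phi)`, predictors i.i.d. uniform
#' on `[0, 10]` (time-varying by default), outcome
#' `y = X beta + tau_i + eps` with stationary AR(1) residuals at the
#' person-specific variance `exp(s0 + omega_i)` and autocorrelation
#' `tanh(r0 + iota_i)`.
#'
#' @param I number of persons.
#' @param T_len occasions per person (scalar or length-`I` vector).
#' @param beta fixed-effect vector; its first element is the intercept and
#'   the rest multiply `length(beta) - 1` uniform predictors named
#'   `x1, x2, ...`.
#' @param s0,r0 location-scale intercepts (log variance, atanh
#'   autocorrelation).
#' @param Phi 3 x 3 positive semidefinite random-effect covariance.
#' @param person_level logical; draw the predictors once per person instead
#'   of at every occasion.
#' @param seed optional RNG seed.
#' @return a [long_data()] object with attribute `truth` (list with the
#'   generating parameters and the per-person random effects).
#' @export
simulate_emels_data <- function(I, T_len, beta, s0, r0, Phi,
                                person_level = FALSE, seed = NULL) {
  stopifnot(I >= 1, all(T_len >= 1), nrow(Phi) == 3, ncol(Phi) == 3)
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("Phi must be positive semidefinite")
  if (!is.null(seed)) set.seed(seed)
  T_len <- rep_len(T_len, I)
  p <- length(beta) - 1L
  ch <- chol(Phi + diag(1e-12, 3))
  V <- matrix(stats::rnorm(3 * I), I, 3) %*% ch
  rows <- vector("list", I)
  for (i in seq_len(I)) {
    Ti <- T_len[i]
    P <- if (p > 0) {
      if (person_level)
        matrix(rep(stats::runif(p, 0, 10), each = Ti), Ti, p)
      else matrix(stats::runif(Ti * p, 0, 10), Ti, p)
    } else matrix(0, Ti, 0)
    sig2 <- person_sigma2(s0, V[i, 2])
    rho <- person_rho(r0, V[i, 3])
    eps <- sim_ar1_vector(Ti, sig2, rho)
    y <- beta[1] + (if (p > 0) drop(P %*% beta[-1]) else 0) + V[i, 1] + eps
    df <- data.frame(id = sprintf("p%03d", i), time = seq_len(Ti), y = y)
    if (p > 0) {
      colnames(P) <- paste0("x", seq_len(p))
      df <- cbind(df, as.data.frame(P))
    }
    rows[[i]] <- df
  }
  d <- do.call(rbind, rows)
  out <- long_data(d, outcome = "y", id = "id", time = "time",
                   predictors = if (p > 0) paste0("x", seq_len(p))
                                else character())
  attr(out, "truth") <- list(beta = beta, s0 = s0, r0 = r0, Phi = Phi,
                             v = V, seed = seed)
  out
}

# The 4-leaf step function on (x1, x2, x3) used by the tree scenario.
tree_leaf_mean <- function(x1, x2, x3) {
  ifelse(x1 <= 5,
         ifelse(x2 <= 5, 10, 11),
         ifelse(x3 <= 5, 12, 13))
}

#' Simulate the 4-leaf tree benchmark scenario
#'
#' Nine predictors i.i.d. uniform on `[0, 10]`, redrawn at every occasion;
#' the outcome follows a 4-leaf regression tree on `x1, x2, x3` (split point
#' 5, leaf means 10, 11, 12, 13), plus a person random intercept and
#' stationary AR(1) residuals with person-specific log variance
#' `s0 + omega_i` and atanh autocorrelation `r0 + iota_i`.  Defaults follow
#' the benchmark design: `I = 200` persons, `T_len = 51` occasions,
#' `s0 = -0.67`, `r0 = 0.26`, random-effect variances `(1.0, 0.5, 0.5)`
#' with zero covariances.
#'
#' @param I,T_len persons and occasions per person.
#' @param s0,r0 location-scale intercepts.
#' @param phi_diag variances of `(tau, omega, iota)`; covariances are zero.
#' @param seed optional RNG seed.
#' @return a [long_data()] object with attribute `truth` (parameters,
#'   per-person random effects, and the per-row leaf index).
#' @export
simulate_tree_data <- function(I = 200, T_len = 51, s0 = -0.67, r0 = 0.26,
                               phi_diag = c(1.0, 0.5, 0.5), seed = NULL) {
  stopifnot(I >= 1, T_len >= 1)
  if (!is.null(seed)) set.seed(seed)
  V <- cbind(stats::rnorm(I, 0, sqrt(phi_diag[1])),
             stats::rnorm(I, 0, sqrt(phi_diag[2])),
             stats::rnorm(I, 0, sqrt(phi_diag[3])))
  rows <- vector("list", I)
  leaf_all <- vector("list", I)
  for (i in seq_len(I)) {
    P <- matrix(stats::runif(T_len * 9, 0, 10), T_len, 9)
    colnames(P) <- paste0("x", 1:9)
    mu <- tree_leaf_mean(P[, 1], P[, 2], P[, 3])
    leaf <- ifelse(P[, 1] <= 5, ifelse(P[, 2] <= 5, 1L, 2L),
                   ifelse(P[, 3] <= 5, 3L, 4L))
    sig2 <- person_sigma2(s0, V[i, 2])
    rho <- person_rho(r0, V[i, 3])
    eps <- sim_ar1_vector(T_len, sig2, rho)
    y <- mu + V[i, 1] + eps
    rows[[i]] <- cbind(data.frame(id = sprintf("p%03d", i),
                                  time = seq_len(T_len), y = y),
                       as.data.frame(P))
    leaf_all[[i]] <- leaf
  }
  d <- do.call(rbind, rows)
  out <- long_data(d, outcome = "y", id = "id", time = "time",
                   predictors = paste0("x", 1:9))
  attr(out, "truth") <- list(s0 = s0, r0 = r0, Phi = diag(phi_diag),
                             v = V, leaf = unlist(leaf_all),
                             leaf_means = c(10, 11, 12, 13), seed = seed)
  out
}

#' Add interaction columns to a long dataset
#'
#' Convenience feature builder appending product columns (e.g. `x1x2`)
#' so that interaction terms can be treated as ordinary predictors by the
#' Lasso path and the preprocessing verbs.
#'
#' @param ld a `long_data` object.
#' @param pairs list of character pairs, e.g. `list(c("x1","x2"))`.
#' @return a new `long_data` with the product columns appended.
#' @export
add_interactions <- function(ld, pairs) {
  d <- as.data.frame(ld)
  preds <- attr(ld, "predictors")
  for (pr in pairs) {
    stopifnot(length(pr) == 2, all(pr %in% names(d)))
    nm <- paste0(pr[1], pr[2])
    d[[nm]] <- d[[pr[1]]] * d[[pr[2]]]
    preds <- c(preds, nm)
  }
  long_data(d, outcome = attr(ld, "outcome"), id = attr(ld, "id"),
            time = attr(ld, "time"), predictors = preds)
}
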