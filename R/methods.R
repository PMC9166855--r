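# S3 methods for fitted location-scale models.

#' @export
print.emels <- function(x, digits = 4, ...) {
  cat(switch(x$model,
             emels = "Extended mixed-effect location-scale model (E-MELS)",
             lmm_ar1 = "Linear mixed-effect model with AR(1) residuals"),
      "\n", sep = "")
  cat("  persons: ", x$n_persons, ", observations: ", x$n_total, "\n", sep = "")
  cat("  logLik: ", format(x$logLik, digits = digits + 3),
      "  AIC: ", format(x$aic, digits = digits + 3),
      "  BIC: ", format(x$bic, digits = digits + 3), "\n", sep = "")
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  cat("\nFixed effects:\n")
  print(round(x$beta, digits))
  cat("\nIntercept variance: ", round(x$Phi[1, 1], digits), "\n", sep = "")
  cat("Residual variance: mean exp(s0) = ", round(exp(x$s0), digits),
      if (x$model == "emels")
        paste0(", between-person variance = ", round(x$Phi[2, 2], digits)),
      "\n", sep = "")
  cat("Autocorrelation: mean tanh(r0) = ", round(tanh(x$r0), digits),
      if (x$model == "emels")
        paste0(", between-person variance = ", round(x$Phi[3, 3], digits)),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.emels <- function(object, ...) {
  structure(list(fit = object, report = object$report),
            class = "summary.emels")
}

#' @export
print.summary.emels <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nParameter table (reporting scale):\n")
  rep_ <- x$report
  rep_$estimate <- round(rep_$estimate, digits)
  rep_$se <- round(rep_$se, digits)
  print(rep_, row.names = FALSE)
  invisible(x)
}

#' @export
coef.emels <- function(object, ...) object$beta

#' @export
logLik.emels <- function(object, ...) {
  structure(object$logLik, df = object$n_params, nobs = object$n_total,
            class = "logLik")
}

#' Covariance matrix of the fixed-effect estimates
#' @param object a fitted `emels` model.
#' @param ... unused.
#' @export
vcov.emels <- function(object, ...) {
  nb <- length(object$beta)
  if (is.null(object$vcov_unconstrained))
    return(matrix(NA_real_, nb, nb,
                  dimnames = list(names(object$beta), names(object$beta))))
  V <- object$vcov_unconstrained[seq_len(nb), seq_len(nb), drop = FALSE]
  dimnames(V) <- list(names(object$beta), names(object$beta))
  V
}

#' Empirical-Bayes random-effect estimates of the training persons
#'
#' Posterior means of \eqn{(\tau_i, \omega_i, \iota_i)} given each person's
#' data at the ML estimates, together with the implied person-specific
#' residual variance and autocorrelation.
#'
#' @param object a fitted `emels` model.
#' @param ... unused.
#' @return data.frame with columns id, tau, omega, iota, sigma2, rho.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.emels <- function(object, ...) object$eb

#' @export
fitted.emels <- function(object, ...) {
  unlist(lapply(seq_along(object$env$persons), function(i) {
    pp <- object$env$persons[[i]]
    drop(pp$X %*% object$beta) + object$eb$tau[i]
  }))
}

#' Residuals of a fitted location-scale model
#'
#' `type = "level1"` returns \eqn{y - X\beta - Z\hat b} (the within-person
#' residuals whose last element seeds the AR(1) part of a forecast);
#' `type = "fixed_free"` returns \eqn{y - Z\hat b} (outcome freed from the
#' random effects but keeping the fixed part, the working response of the
#' tree algorithm).
#'
#' @param object a fitted `emels` model.
#' @param type residual flavour, see Details.
#' @param ... unused.
#' @export
residuals.emels <- function(object, type = c("level1", "fixed_free"), ...) {
  type <- match.arg(type)
  unlist(lapply(seq_along(object$env$persons), function(i) {
    pp <- object$env$persons[[i]]
    if (type == "level1")
      pp$y - drop(pp$X %*% object$beta) - object$eb$tau[i]
    else
      pp$y - object$eb$tau[i]
  }))
}

#' Likelihood-ratio test between nested fits
#'
#' @param fit_full the richer model (e.g. the location-scale model).
#' @param fit_nested the nested model (e.g. the AR(1) linear mixed model).
#' @return list with `statistic`, `df` and `p.value`.
#' @export
lr_test <- function(fit_full, fit_nested) {
  stopifnot(inherits(fit_full, "emels"), inherits(fit_nested, "emels"))
  stat <- 2 * (fit_full$logLik - fit_nested$logLik)
  if (stat < -1e-6)
    stop("full model has lower log-likelihood than the nested model; ",
         "check convergence")
  stat <- max(stat, 0)
  df <- fit_full$n_params - fit_nested$n_params
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' @export
anova.emels <- function(object, ...) {
  fits <- c(list(object), list(...))
  fits <- Filter(function(f) inherits(f, "emels"), fits)
  if (length(fits) != 2)
    stop("supply exactly two nested fits")
  ord <- order(vapply(fits, `[[`, 0, "n_params"))
  nested <- fits[[ord[1]]]; full <- fits[[ord[2]]]
  lt <- lr_test(full, nested)
  out <- data.frame(
    df = c(nested$n_params, full$n_params),
    logLik = c(nested$logLik, full$logLik),
    AIC = c(nested$aic, full$aic),
    BIC = c(nested$bic, full$bic),
    Chisq = c(NA, lt$statistic),
    `Chi Df` = c(NA, lt$df),
    `Pr(>Chisq)` = c(NA, lt$p.value),
    check.names = FALSE,
    row.names = c("nested", "full"))
  class(out) <- c("anova", "data.frame")
  out
}

#' Simulate new datasets from a fitted model
#'
#' Draws complete new datasets (new random effects, new AR(1) residuals)
#' from the fitted parameters, over the same persons and designs as the
#' training data.
#'
#' @param object a fitted `emels` model.
#' @param nsim number of datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of `nsim` data.frames with columns id, time, y.
#' @export
simulate.emels <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Phi <- object$Phi
  # guard exact zeros of the nested model
  ch <- chol(Phi + diag(1e-12, 3))
  lapply(seq_len(nsim), function(s) {
    do.call(rbind, lapply(object$env$persons, function(pp) {
      v <- drop(crossprod(ch, stats::rnorm(3)))
      sig2 <- person_sigma2(object$s0, v[2])
      rho <- person_rho(object$r0, v[3])
      eps <- sim_ar1_vector(pp$T_len, sig2, rho)
      data.frame(id = pp$id, time = seq_len(pp$T_len),
                 y = drop(pp$X %*% object$beta) + v[1] + eps)
    }))
  })
}

#' Plot empirical-Bayes person profiles
#'
#' Scatter of the per-person residual SD against the per-person lag-1
#' autocorrelation implied by the empirical-Bayes estimates: the two
#' stability components the model separates.
#'
#' @param x a fitted `emels` model.
#' @param ... passed to [plot()].
#' @export
plot.emels <- function(x, ...) {
  eb <- x$eb
  plot(sqrt(eb$sigma2), eb$rho,
       xlab = "person residual SD (EB)",
       ylab = "person lag-1 autocorrelation (EB)",
       main = "Between-person location-scale heterogeneity", ...)
  graphics::abline(h = tanh(x$r0), v = sqrt(exp(x$s0)), lty = 3)
  invisible(x)
}
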