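# Empirical-Bayes estimation for arbitrary series, H-step forecasting for
# the three prediction tasks, forecast-error variances, and evaluation.
#
# Task 1: future occasion of a person in the training sample.
# Task 2: new person without history (fixed effects only).
# Task 3: new person whose history is used for empirical-Bayes estimation
#         with the training-sample parameters, then the Task-1 formula.
#
# Point forecast (Tasks 1/3):  y_hat = x'beta + b_hat + rho_i^H * eps_hat_T,
# with rho_i the person-specific EB autocorrelation and eps_hat_T the last
# level-1 residual of the history.

# Posterior mean of v = (tau, omega, iota) for one series at the fitted
# parameters.  AGH posterior mean for the location-scale model; for the
# AR(1)-LMM the closed form Phi Z' V^{-1} (y - X beta).
eb_core <- function(object, y, X) {
  if (object$model == "lmm_ar1") {
    env1 <- emels_env(list(list(id = "new", y = y, X = X)))
    tau <- lmm_eb(env1, object$par_lmm)
    return(c(tau = unname(tau), omega = 0, iota = 0))
  }
  theta <- object$theta
  pp <- prep_series(list(list(id = "new", y = y, X = X)))[[1]]
  ss <- suffstats(pp, theta$beta)
  prior <- prior_prep(object$Phi)
  rule <- adapt_person(pp, ss, theta$s0, theta$r0, prior)
  pm <- person_marginal(pp, ss, theta, prior, rule, object$grid,
                        want_grad = TRUE)
  v <- colSums(pm$wt * pm$V)
  c(tau = v[1], omega = v[2], iota = v[3])
}

#' Empirical-Bayes random effects for new persons
#'
#' Estimates the random effects of persons not in the training sample from
#' their observed history, using the training-sample parameter estimates
#' (the Task-3 ingredient).
#'
#' @param object a fitted `emels` (or tree) model.
#' @param newdata long-format data.frame with the same id, time, outcome and
#'   predictor columns as the training data.
#' @param ... unused.
#' @return data.frame with one row per person: id, tau, omega, iota, and the
#'   implied sigma2 and rho.
#' @export
eb_estimate <- function(object, newdata, ...) UseMethod("eb_estimate")

#' @rdname eb_estimate
#' @export
eb_estimate.emels <- function(object, newdata, ...) {
  ms <- model_series(object, newdata, need_outcome = TRUE)
  out <- do.call(rbind, lapply(ms, function(s) {
    v <- eb_core(object, s$y, s$X)
    data.frame(id = s$id, tau = v[1], omega = v[2], iota = v[3],
               stringsAsFactors = FALSE)
  }))
  out$sigma2 <- person_sigma2(object$s0, out$omega)
  out$rho <- person_rho(object$r0, out$iota)
  rownames(out) <- NULL
  out
}

# Build per-person series from a new data.frame using the fit's terms.
model_series <- function(object, data, need_outcome = FALSE) {
  d <- as.data.frame(data)
  idc <- attr(object$ld, "id"); tmc <- attr(object$ld, "time")
  outc <- attr(object$ld, "outcome")
  if (!idc %in% names(d)) stop("column '", idc, "' missing from data")
  trms <- stats::delete.response(object$terms)
  mf <- stats::model.frame(trms, d)
  X <- stats::model.matrix(trms, mf)
  if (!is.null(object$x_cols)) X <- X[, object$x_cols, drop = FALSE]
  ids <- d[[idc]]
  lapply(unique(ids), function(pid) {
    rows <- which(ids == pid)
    ord <- order(d[[tmc]][rows])
    rows <- rows[ord]
    list(id = as.character(pid),
         times = d[[tmc]][rows],
         y = if (need_outcome) d[[outc]][rows] else NULL,
         X = X[rows, , drop = FALSE])
  })
}

# Forecast-error variance, Tasks 1 and 3: fixed-effect uncertainty with the
# GLS shrinkage weight, random-effect prediction variance, and the
# (unconditional, stationary) future residual variance.
fev_task13 <- function(x_fut, X_hist, covb, phi2_tau, sig2_i, rho_i,
                       H) {
  T_len <- nrow(X_hist)
  c_i <- sig2_i / (1 - rho_i^2)
  V <- phi2_tau + ar1_covariance(sig2_i, rho_i, T_len)
  Vi_X <- solve(V, X_hist)
  Vi_1 <- solve(V, rep(1, T_len))
  covvec <- c_i * rho_i^seq(T_len + H - 1, H)
  C <- phi2_tau + covvec
  A <- x_fut - drop(C %*% Vi_X)
  term1 <- if (all(is.finite(covb))) drop(A %*% covb %*% A) else NA_real_
  term2 <- phi2_tau - phi2_tau^2 * sum(Vi_1)
  term1 + term2 + c_i
}

# Forecast-error variance, Task 2: no history, so fixed-effect uncertainty
# plus the full random-intercept variance plus the stationary residual
# variance.
fev_task2 <- function(x_fut, covb, phi2_tau, sig2, rho) {
  term1 <- if (all(is.finite(covb))) drop(x_fut %*% covb %*% x_fut)
           else NA_real_
  term1 + phi2_tau + sig2 / (1 - rho^2)
}

#' Forecast future occasions
#'
#' @param object a fitted model.
#' @param ... further arguments passed to methods.
#' @export
forecast <- function(object, ...) UseMethod("forecast")

#' H-step forecasts from a fitted location-scale model
#'
#' @param object a fitted `emels` model.
#' @param future data.frame of future rows: one row per forecast, containing
#'   the id, time and predictor columns (the future design is assumed
#'   known).  If the outcome column is present it is carried along as
#'   `observed`.
#' @param task prediction task: 1 (trained person), 2 (new person, no
#'   history), 3 (new person with history).
#' @param history for task 3, a long-format data.frame with the past
#'   occasions of the persons in `future`.  For task 1 the training data
#'   stored in the fit are used.  Ignored for task 2.
#' @param se compute the forecast-error variance (and its square root
#'   `sigma_F`).
#' @param ... unused.
#' @return data.frame with columns id, task, H, y_hat, var_hat, sigma_F and,
#'   when available, observed.
#' @export
forecast.emels <- function(object, future, task = 1, history = NULL,
                           se = TRUE, ...) {
  stopifnot(task %in% 1:3)
  d <- as.data.frame(future)
  if (nrow(d) == 0) stop("no future rows supplied")
  idc <- attr(object$ld, "id"); tmc <- attr(object$ld, "time")
  outc <- attr(object$ld, "outcome")
  trms <- stats::delete.response(object$terms)
  Xf <- stats::model.matrix(trms, stats::model.frame(trms, d))
  if (!is.null(object$x_cols)) Xf <- Xf[, object$x_cols, drop = FALSE]
  covb <- vcov(object)
  phi2_tau <- object$Phi[1, 1]

  hist_map <- NULL
  if (task == 1) {
    hist_map <- stats::setNames(object$env$persons,
                                vapply(object$env$persons,
                                       function(p) as.character(p$id), ""))
    eb_map <- object$eb
  } else if (task == 3) {
    if (is.null(history) || nrow(as.data.frame(history)) == 0)
      stop("task 3 requires a non-empty history; ",
           "use task = 2 for persons without past observations")
    hs <- model_series(object, history, need_outcome = TRUE)
    hist_map <- stats::setNames(hs, vapply(hs, `[[`, "", "id"))
    eb_map <- eb_estimate(object, history)
  }

  out <- lapply(seq_len(nrow(d)), function(i) {
    pid <- as.character(d[[idc]][i])
    x_fut <- Xf[i, ]
    obs <- if (outc %in% names(d)) d[[outc]][i] else NA_real_
    if (task == 2) {
      y_hat <- drop(x_fut %*% object$beta)
      var_hat <- if (se)
        fev_task2(x_fut, covb, phi2_tau, exp(object$s0), tanh(object$r0))
        else NA_real_
      return(data.frame(id = pid, task = 2, H = NA_real_, y_hat = y_hat,
                        var_hat = var_hat, observed = obs,
                        stringsAsFactors = FALSE))
    }
    ps <- hist_map[[pid]]
    if (is.null(ps))
      stop("person '", pid, "' has no ",
           if (task == 1) "training" else "history", " series; ",
           "use task = 2 for persons without past observations")
    eb_row <- eb_map[match(pid, eb_map$id), ]
    T_len <- length(ps$y)
    H <- d[[tmc]][i] - max(ps$times)
    if (!is.finite(H) || H < 1)
      stop("future time must lie after the last history occasion (person '",
           pid, "')")
    sig2_i <- eb_row$sigma2
    rho_i <- eb_row$rho
    eps_T <- ps$y[T_len] - drop(ps$X[T_len, ] %*% object$beta) - eb_row$tau
    y_hat <- drop(x_fut %*% object$beta) + eb_row$tau + rho_i^H * eps_T
    var_hat <- if (se)
      fev_task13(x_fut, ps$X, covb, phi2_tau, sig2_i, rho_i, H)
      else NA_real_
    data.frame(id = pid, task = task, H = H, y_hat = y_hat,
               var_hat = var_hat, observed = obs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$sigma_F <- sqrt(pmax(out$var_hat, 0))
  rownames(out) <- NULL
  out[, c("id", "task", "H", "y_hat", "var_hat", "sigma_F", "observed")]
}

#' @export
predict.emels <- function(object, newdata = NULL, task = 1, history = NULL,
                          ...) {
  if (is.null(newdata)) return(fitted(object))
  forecast(object, future = newdata, task = task, history = history, ...)$y_hat
}

#' Forecast accuracy and precision summaries
#'
#' Mean squared forecast error, its standard error (SD of the squared
#' errors over the square root of the number of forecasts), and the average
#' forecast-error standard deviation `sigma_F`.
#'
#' @param forecasts a data.frame from [forecast.emels()] (columns `y_hat`,
#'   `sigma_F`, and `observed` unless `observed` is supplied separately).
#' @param observed optional numeric vector of realized outcomes aligned
#'   with `forecasts`.
#' @return list with `mse`, `mse_se`, `mean_sigma_F` and `m`.
#' @export
evaluate_forecasts <- function(forecasts, observed = NULL) {
  if (is.null(observed)) observed <- forecasts$observed
  y_hat <- if (is.data.frame(forecasts)) forecasts$y_hat else forecasts
  if (length(y_hat) == 0) stop("no forecasts to evaluate")
  if (length(observed) != length(y_hat) || anyNA(observed))
    stop("observed outcomes missing or misaligned")
  sq <- (observed - y_hat)^2
  sF <- if (is.data.frame(forecasts)) forecasts$sigma_F else NULL
  list(mse = mean(sq),
       mse_se = stats::sd(sq) / sqrt(length(sq)),
       mean_sigma_F = if (!is.null(sF) && any(is.finite(sF)))
         mean(sF, na.rm = TRUE) else NA_real_,
       m = length(sq))
}

# Split new persons into history (all but the last occasion) and future
# (the last occasion), for Task-2/3 evaluation.
last_occasion_split <- function(ld) {
  d <- as.data.frame(ld)
  idc <- attr(ld, "id"); tmc <- attr(ld, "time")
  last <- stats::ave(d[[tmc]], d[[idc]], FUN = max) == d[[tmc]]
  list(history = d[!last, , drop = FALSE],
       future = d[last, , drop = FALSE])
}

#' One-step-ahead benchmark across models and prediction tasks
#'
#' Reproduces the standard accuracy/precision table: for every fitted model
#' and every task, the one-step-ahead MSE (with its standard error) and the
#' mean forecast-error SD `sigma_F`.  `sigma_F` is reported as `NA` for tree
#' models, for which no forecast-error variance is available.
#'
#' @param fits named list of fitted models (`emels`, `mem_ar1` or
#'   `emels_tree` objects), all trained on the same training sample.
#' @param split a list as returned by [split_train_test()]: `train`,
#'   `test_task1` (future occasions of training persons) and
#'   `test_newpersons` (full series of held-out persons).
#' @return data.frame with one row per model x task: mse, mse_se, sigma_F, m.
#' @export
forecast_benchmark <- function(fits, split) {
  stopifnot(length(names(fits)) == length(fits))
  np <- last_occasion_split(split$test_newpersons)
  rows <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    per_task <- lapply(1:3, function(tk) {
      fc <- switch(tk,
        forecast(fit, future = split$test_task1, task = 1),
        forecast(fit, future = np$future, task = 2),
        forecast(fit, future = np$future, task = 3, history = np$history))
      ev <- evaluate_forecasts(fc)
      data.frame(model = nm, task = tk, mse = ev$mse, mse_se = ev$mse_se,
                 sigma_F = ev$mean_sigma_F, m = ev$m,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_task)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
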