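# CART regression trees (grown and CV-pruned via rpart) and the alternating
# location-scale tree algorithm:
#   step 1  fit a tree to the random-effect-freed residuals y - Z b_hat
#   step 2  re-express the tree as leaf-membership dummies and fit the
#           location-scale model (or the AR(1)-LMM) on them
# iterated until the model log-likelihood stabilizes.

#' Fit a CV-pruned CART regression tree
#'
#' Greedy binary splitting minimizing within-node SSE (via rpart), with a
#' split admitted only in nodes with at least `minsplit` rows and kept only
#' if it improves the relative error by at least `cp`; the full tree is then
#' cost-complexity pruned to the subtree with the smallest `cv_folds`-fold
#' cross-validation error (no 1-SE rule).
#'
#' @param x data.frame of predictor columns.
#' @param y numeric response.
#' @param cp complexity parameter (relative SSE improvement threshold).
#' @param minsplit minimum rows in a node for a split to be attempted
#'   (minimum rows per leaf is `floor(minsplit / 3)`, the CART convention).
#' @param cv_folds cross-validation folds for pruning (0 disables pruning).
#' @param seed optional seed controlling the CV fold assignment.
#' @return object of class `cart_fit`: the pruned tree plus a leaf table
#'   (leaf node number, mean, n).
#' @export
fit_cart <- function(x, y, cp = 0.001, minsplit = 20, cv_folds = 10,
                     seed = NULL) {
  if (minsplit < 2) stop("minsplit must be at least 2")
  stopifnot(is.data.frame(x), nrow(x) == length(y), nrow(x) >= 1)
  if (!is.null(seed)) set.seed(seed)
  df <- cbind(.y = y, x)
  rp <- rpart::rpart(.y ~ ., data = df, method = "anova",
                     control = rpart::rpart.control(
                       cp = cp, minsplit = minsplit,
                       minbucket = max(floor(minsplit / 3), 1),
                       xval = cv_folds,
                       maxcompete = 0, maxsurrogate = 0))
  if (cv_folds > 1 && !is.null(rp$cptable) && "xerror" %in% colnames(rp$cptable)) {
    best <- which.min(rp$cptable[, "xerror"])
    rp <- rpart::prune(rp, cp = rp$cptable[best, "CP"])
  }
  leaves <- rownames(rp$frame)[rp$frame$var == "<leaf>"]
  structure(list(
    rpart = rp,
    leaf_nodes = as.integer(leaves),
    leaf_means = stats::setNames(rp$frame$yval[rp$frame$var == "<leaf>"],
                                 leaves),
    leaf_n = stats::setNames(rp$frame$n[rp$frame$var == "<leaf>"], leaves),
    G = length(leaves),
    feature_names = names(x)), class = "cart_fit")
}

# Route rows through an rpart tree by replaying its primary split rules;
# returns the terminal node number of every row.  (ncat = -1: left child is
# x < split value; ncat = +1: left child is x >= split value.)
route_rpart <- function(rp, newdata) {
  frame <- rp$frame
  node_nums <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  if (all(is_leaf)) return(rep(1L, nrow(newdata)))
  split_row <- integer(nrow(frame))
  srow <- 1L
  for (j in seq_len(nrow(frame))) {
    if (!is_leaf[j]) {
      split_row[j] <- srow
      srow <- srow + frame$ncompete[j] + frame$nsurrogate[j] + 1L
    }
  }
  vars <- as.character(frame$var)
  out <- integer(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    node <- 1L
    repeat {
      j <- match(node, node_nums)
      if (is_leaf[j]) break
      sp <- rp$splits[split_row[j], ]
      xv <- newdata[[vars[j]]][i]
      goleft <- if (sp[["ncat"]] < 0) xv < sp[["index"]] else xv >= sp[["index"]]
      node <- if (goleft) 2L * node else 2L * node + 1L
    }
    out[i] <- node
  }
  out
}

#' Predict from a CART fit
#'
#' @param object a `cart_fit`.
#' @param newdata data.frame containing the tree's predictor columns.
#' @param type `"mean"` for leaf means, `"leaf"` for the leaf index
#'   (1..G, in leaf-node order).
#' @param ... unused.
#' @export
predict.cart_fit <- function(object, newdata,
                             type = c("mean", "leaf"), ...) {
  type <- match.arg(type)
  nodes <- route_rpart(object$rpart, as.data.frame(newdata))
  gi <- match(nodes, object$leaf_nodes)
  if (type == "leaf") gi else unname(object$leaf_means[gi])
}

#' @export
print.cart_fit <- function(x, ...) {
  cat("CART regression tree with", x$G, "terminal node(s)\n")
  print(x$rpart)
  invisible(x)
}

# Leaf-membership dummy matrix (one column per leaf, no intercept).
leaf_dummies <- function(cart, leaf_idx) {
  G <- cart$G
  D <- matrix(0, length(leaf_idx), G)
  D[cbind(seq_along(leaf_idx), leaf_idx)] <- 1
  colnames(D) <- paste0("leaf", seq_len(G))
  D
}

#' Fit a location-scale regression-tree model
#'
#' Alternates between (1) a CART fit to the residuals freed from the
#' current random-intercept estimates (`y - b_hat`, the fixed part is kept)
#' and (2) a location-scale model (or AR(1)-LMM) on the leaf-membership
#' dummy design, updating the empirical-Bayes intercepts, until the model
#' log-likelihood changes by less than `tol` (relative) or `max_alt`
#' alternations are reached.
#'
#' @param formula outcome and the predictors offered to the tree, e.g.
#'   `y ~ x1 + x2 + x3` (predictors are used as splitting features; no
#'   linear terms are fitted).
#' @param data a long-format data.frame or `long_data` object.
#' @param id,time column names (ignored for `long_data` input).
#' @param model `"emels"` for the location-scale model on the dummies,
#'   `"lmm_ar1"` for the plain AR(1) linear mixed model (RE-EM-style tree).
#' @param Q quadrature nodes per dimension for the location-scale fits.
#' @param cp,minsplit,cv_folds CART controls, see [fit_cart()].
#' @param seed seed for the CV fold assignment.
#' @param tol relative log-likelihood change declaring the alternation
#'   converged.
#' @param max_alt maximum number of alternations.
#' @param control controls for the inner model fits (see [emels()]).
#' @return object of class `emels_tree`: the final tree, the inner model
#'   fit on its leaf dummies, the log-likelihood trace across alternations,
#'   and the empirical-Bayes effects.
#' @export
emels_tree <- function(formula = NULL, data, id = "id", time = "time",
                       model = c("emels", "lmm_ar1"), Q = 10L,
                       cp = 0.001, minsplit = 20, cv_folds = 10,
                       seed = NULL, tol = 1e-4, max_alt = 10L,
                       control = list()) {
  model <- match.arg(model)
  if (inherits(data, "long_data") && (missing(formula) || is.null(formula))) {
    preds <- attr(data, "predictors")
    formula <- stats::reformulate(preds, response = attr(data, "outcome"))
  }
  if (inherits(data, "long_data")) {
    ld <- data
  } else {
    vars <- all.vars(formula)
    outcome <- all.vars(formula[[2]])
    ld <- long_data(data, outcome = outcome, id = id, time = time,
                    predictors = setdiff(intersect(vars, names(data)),
                                         c(outcome, id, time)))
  }
  d <- as.data.frame(ld)
  idc <- attr(ld, "id"); tmc <- attr(ld, "time")
  outc <- attr(ld, "outcome")
  features <- setdiff(all.vars(formula), c(outc, idc, tmc))
  xdf <- d[features]
  y <- d[[outc]]
  ids <- d[[idc]]
  uid <- unique(ids)
  person_of_row <- match(ids, uid)

  b_hat <- numeric(length(uid))
  trace <- numeric(0)
  ll_prev <- -Inf
  cart <- NULL
  inner <- NULL
  prev_theta <- NULL
  n_alt <- 0L
  for (alt in seq_len(max_alt)) {
    n_alt <- alt
    resid_free <- y - b_hat[person_of_row]
    cart <- fit_cart(xdf, resid_free, cp = cp, minsplit = minsplit,
                     cv_folds = cv_folds,
                     seed = if (is.null(seed)) NULL else seed + alt)
    leaf_idx <- predict(cart, xdf, type = "leaf")
    D <- leaf_dummies(cart, leaf_idx)
    series <- lapply(seq_along(uid), function(k) {
      rows <- which(person_of_row == k)
      list(id = uid[k], y = y[rows], X = D[rows, , drop = FALSE],
           times = d[[tmc]][rows])
    })
    if (model == "emels") {
      init <- if (!is.null(prev_theta))
        theta_new(stats::setNames(unname(cart$leaf_means),
                                  colnames(D)),
                  prev_theta$s0, prev_theta$r0, prev_theta$lchol)
        else NULL
      inner <- emels_fit_core(series, Q = Q, init = init, control = control)
      ll <- inner$logLik
      prev_theta <- inner$theta
      b_hat <- inner$eb[, 1]
    } else {
      par_init <- if (!is.null(prev_theta))
        c(unname(cart$leaf_means), prev_theta$s0, prev_theta$r0,
          prev_theta$ltau)
        else NULL
      inner <- lmm_fit_core(series, par_init)
      ll <- inner$logLik
      nb <- ncol(D)
      prev_theta <- list(s0 = inner$par[nb + 1], r0 = inner$par[nb + 2],
                         ltau = inner$par[nb + 3])
      b_hat <- inner$tau
    }
    trace <- c(trace, ll)
    if (is.finite(ll) && abs(ll - ll_prev) < tol * (abs(ll) + 1)) break
    ll_prev <- ll
  }

  G <- cart$G
  if (model == "emels") {
    theta <- inner$theta
    Phi <- phi_from_lchol(theta$lchol, 3L)
    eb <- as.data.frame(inner$eb)
    eb$id <- rownames(inner$eb)
    eb$sigma2 <- person_sigma2(theta$s0, eb$omega)
    eb$rho <- person_rho(theta$r0, eb$iota)
    obj <- list(model = "emels", tree = cart, theta = theta, Phi = Phi,
                beta = theta$beta, s0 = theta$s0, r0 = theta$r0,
                logLik = inner$logLik,
                n_params = n_free_params(G, 3L),
                env = inner$env, grid = inner$grid, rules = inner$rules,
                eb = eb[, c("id", "tau", "omega", "iota", "sigma2", "rho")],
                Q = Q)
  } else {
    par <- inner$par
    s0 <- par[G + 1]; r0 <- par[G + 2]; phi2 <- exp(2 * par[G + 3])
    eb <- data.frame(id = as.character(uid), tau = inner$tau,
                     omega = 0, iota = 0, sigma2 = exp(s0), rho = tanh(r0),
                     stringsAsFactors = FALSE)
    obj <- list(model = "lmm_ar1", tree = cart,
                beta = stats::setNames(par[seq_len(G)],
                                       paste0("leaf", seq_len(G))),
                s0 = s0, r0 = r0,
                Phi = diag(c(phi2, 0, 0)),
                par_lmm = par,
                logLik = inner$logLik, n_params = G + 3L,
                env = inner$env, grid = NULL, rules = NULL,
                eb = eb, Q = NA_integer_)
  }
  obj$theta <- obj$theta %||% NULL
  obj$trace <- trace
  obj$n_alternations <- n_alt
  obj$converged <- n_alt < max_alt ||
    abs(trace[n_alt] - (if (n_alt > 1) trace[n_alt - 1] else -Inf)) <
      tol * (abs(trace[n_alt]) + 1)
  obj$ld <- ld
  obj$features <- features
  obj$n_total <- length(y)
  obj$n_persons <- length(uid)
  obj$aic <- -2 * obj$logLik + 2 * obj$n_params
  obj$bic <- -2 * obj$logLik + log(length(y)) * obj$n_params
  obj$call <- match.call()
  class(obj) <- "emels_tree"
  obj
}

#' @export
print.emels_tree <- function(x, digits = 4, ...) {
  cat("Location-scale regression-tree model (",
      if (x$model == "emels") "E-MELS" else "AR(1)-LMM",
      " on leaf dummies)\n", sep = "")
  cat("  alternations: ", x$n_alternations,
      ", terminal nodes: ", x$tree$G, "\n", sep = "")
  cat("  logLik: ", format(x$logLik, digits = digits + 3), "\n", sep = "")
  cat("  leaf means (model estimates):\n")
  print(round(x$beta, digits))
  cat("\nResidual variance: mean exp(s0) = ", round(exp(x$s0), digits),
      ";  autocorrelation: mean tanh(r0) = ", round(tanh(x$r0), digits),
      "\n", sep = "")
  invisible(x)
}

#' @export
logLik.emels_tree <- function(object, ...) {
  structure(object$logLik, df = object$n_params, nobs = object$n_total,
            class = "logLik")
}

#' @export
coef.emels_tree <- function(object, ...) object$beta

#' @export
predict.emels_tree <- function(object, newdata, ...) {
  gi <- predict(object$tree, as.data.frame(newdata), type = "leaf")
  unname(object$beta[gi])
}

#' @rdname eb_estimate
#' @export
eb_estimate.emels_tree <- function(object, newdata, ...) {
  d <- as.data.frame(newdata)
  idc <- attr(object$ld, "id"); tmc <- attr(object$ld, "time")
  outc <- attr(object$ld, "outcome")
  gi <- predict(object$tree, d, type = "leaf")
  D <- leaf_dummies(object$tree, gi)
  out <- do.call(rbind, lapply(unique(d[[idc]]), function(pid) {
    rows <- which(d[[idc]] == pid)
    rows <- rows[order(d[[tmc]][rows])]
    v <- eb_core(object, d[[outc]][rows], D[rows, , drop = FALSE])
    data.frame(id = as.character(pid), tau = v[1], omega = v[2], iota = v[3],
               stringsAsFactors = FALSE)
  }))
  out$sigma2 <- person_sigma2(object$s0, out$omega)
  out$rho <- person_rho(object$r0, out$iota)
  rownames(out) <- NULL
  out
}

#' Forecasts from a fitted tree model
#'
#' The Task-1/3 point forecast applies the person's empirical-Bayes
#' intercept and autocorrelated residual on top of the model-estimated leaf
#' mean of the future row.  No forecast-error variance is reported for tree
#' models (`var_hat` and `sigma_F` are `NA`).
#'
#' @inheritParams forecast.emels
#' @export
forecast.emels_tree <- function(object, future, task = 1, history = NULL,
                                ...) {
  stopifnot(task %in% 1:3)
  d <- as.data.frame(future)
  if (nrow(d) == 0) stop("no future rows supplied")
  idc <- attr(object$ld, "id"); tmc <- attr(object$ld, "time")
  outc <- attr(object$ld, "outcome")
  mu_fut <- predict(object, d)

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
    h <- as.data.frame(history)
    gi <- predict(object$tree, h, type = "leaf")
    Dh <- leaf_dummies(object$tree, gi)
    hs <- lapply(unique(h[[idc]]), function(pid) {
      rows <- which(h[[idc]] == pid)
      rows <- rows[order(h[[tmc]][rows])]
      list(id = as.character(pid), times = h[[tmc]][rows],
           y = h[[outc]][rows], X = Dh[rows, , drop = FALSE])
    })
    hist_map <- stats::setNames(hs, vapply(hs, `[[`, "", "id"))
    eb_map <- eb_estimate(object, h)
  }

  out <- lapply(seq_len(nrow(d)), function(i) {
    pid <- as.character(d[[idc]][i])
    obs <- if (outc %in% names(d)) d[[outc]][i] else NA_real_
    if (task == 2)
      return(data.frame(id = pid, task = 2, H = NA_real_, y_hat = mu_fut[i],
                        var_hat = NA_real_, observed = obs,
                        stringsAsFactors = FALSE))
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
    eps_T <- ps$y[T_len] - drop(ps$X[T_len, ] %*% object$beta) - eb_row$tau
    y_hat <- mu_fut[i] + eb_row$tau + eb_row$rho^H * eps_T
    data.frame(id = pid, task = task, H = H, y_hat = y_hat,
               var_hat = NA_real_, observed = obs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$sigma_F <- NA_real_
  rownames(out) <- NULL
  out[, c("id", "task", "H", "y_hat", "var_hat", "sigma_F", "observed")]
}
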