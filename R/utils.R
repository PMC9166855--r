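# Small numerical helpers shared across the estimation code.

#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights for the weight function exp(-x^2), computed by the
#' Golub-Welsch eigendecomposition of the Jacobi matrix.
#'
#' @param Q number of nodes (>= 1).
#' @return list with `nodes` and `weights`, both length `Q`.
#' @keywords internal
#' @noRd
gauss_hermite <- function(Q) {
  stopifnot(Q >= 1)
  if (Q == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(Q - 1)
  off <- sqrt(i / 2)
  J <- matrix(0, Q, Q)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Central finite-difference gradient with per-coordinate relative steps.
num_grad <- function(f, x, h = NULL, ...) {
  if (is.null(h)) h <- 1e-5 * pmax(1, abs(x))
  h <- rep_len(h, length(x))
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- x[j] + h[j]
    xm <- x; xm[j] <- x[j] - h[j]
    g[j] <- (f(xp, ...) - f(xm, ...)) / (2 * h[j])
  }
  g
}

# Central finite-difference Hessian of a scalar function.
num_hessian <- function(f, x, h = NULL, ...) {
  n <- length(x)
  if (is.null(h)) h <- 1e-4 * pmax(1, abs(x))
  h <- rep_len(h, n)
  H <- matrix(0, n, n)
  f0 <- f(x, ...)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp, ...) - 2 * f0 + f(xm, ...)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp, ...) - f(xpm, ...) - f(xmp, ...) + f(xmm, ...)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

`%||%` <- function(a, b) if (is.null(a)) b else a
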