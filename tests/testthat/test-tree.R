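# CART wrapper, routing, and the alternating location-scale tree.

test_that("degenerate responses give a single leaf", {
  x <- data.frame(x1 = runif(60, 0, 10))
  ct <- fit_cart(x, rep(3.5, 60), cv_folds = 0)
  expect_equal(ct$G, 1L)
  expect_equal(unname(ct$leaf_means), 3.5)
  expect_equal(predict(ct, data.frame(x1 = c(-5, 20))), c(3.5, 3.5))
  expect_error(fit_cart(x, rep(1, 60), minsplit = 1), "minsplit")
})

test_that("the root split matches exhaustive SSE search", {
  set.seed(41)
  for (rep in 1:3) {
    n <- c(120, 300, 500)[rep]
    x <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10),
                    x3 = runif(n, 0, 10))
    y <- ifelse(x$x1 < 5, 0, 1) + 0.3 * x$x2 + rnorm(n, 0, 0.4)
    ct <- fit_cart(x, y, cv_folds = 0, minsplit = 20)
    rp <- ct$rpart
    # SSE achieved by the fitted root split
    root_var <- as.character(rp$frame$var[1])
    sp <- rp$splits[1, ]
    left <- if (sp[["ncat"]] < 0) x[[root_var]] < sp[["index"]]
            else x[[root_var]] >= sp[["index"]]
    sse_fit <- sum((y[left] - mean(y[left]))^2) +
      sum((y[!left] - mean(y[!left]))^2)
    sse_best <- brute_best_split(x, y, minbucket = floor(20 / 3))
    expect_equal(sse_fit, sse_best, tolerance = 1e-10)
  }
})

test_that("two-region step data recover the step", {
  set.seed(42)
  n <- 200
  x <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10))
  y <- ifelse(x$x1 < 5, 0, 1) + rnorm(n, 0, 0.15)
  ct <- fit_cart(x, y, seed = 1)
  expect_equal(as.character(ct$rpart$frame$var[1]), "x1")
  expect_lt(abs(ct$rpart$splits[1, "index"] - 5), 0.6)
  means <- sort(range(ct$leaf_means))
  expect_lt(abs(means[1] - 0), 0.15)
  expect_lt(abs(means[2] - 1), 0.15)
})

test_that("routing agrees with region membership and training means", {
  set.seed(43)
  n <- 400
  x <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10),
                  x3 = runif(n, 0, 10))
  y <- emx("tree_leaf_mean")(x$x1, x$x2, x$x3) + rnorm(n, 0, 0.5)
  ct <- fit_cart(x, y, seed = 2)
  # training rows -> predictions equal the leaf means of rpart exactly
  expect_equal(predict(ct, x), unname(predict(ct$rpart, x)))
  # new rows route identically to rpart's own prediction
  xn <- data.frame(x1 = runif(300, 0, 10), x2 = runif(300, 0, 10),
                   x3 = runif(300, 0, 10))
  expect_equal(predict(ct, xn), unname(predict(ct$rpart, xn)))
  # leaf indices partition the rows
  gi <- predict(ct, x, type = "leaf")
  expect_true(all(gi %in% seq_len(ct$G)))
  # leaf means are the means of the training rows routed to each leaf
  for (g in seq_len(ct$G))
    expect_equal(mean(y[gi == g]), unname(ct$leaf_means[g]), tolerance = 1e-10)
})

test_that("cost-complexity pruning returns a subtree", {
  set.seed(44)
  n <- 300
  x <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10))
  y <- ifelse(x$x1 < 5, 0, 1) + rnorm(n)
  full <- fit_cart(x, y, cp = 1e-4, minsplit = 6, cv_folds = 0)
  pruned <- fit_cart(x, y, cp = 1e-4, minsplit = 6, cv_folds = 10, seed = 3)
  expect_lte(pruned$G, full$G)
  expect_true(all(pruned$leaf_nodes %in%
                    c(full$leaf_nodes,
                      as.integer(rownames(full$rpart$frame)))))
})

test_that("alternating tree fit recovers structure and converges", {
  # moderate version of the 4-leaf benchmark scenario
  ld <- simulate_tree_data(I = 40, T_len = 25, seed = 45)
  tf <- emels_tree(y ~ x1 + x2 + x3 + x4 + x5, ld, Q = 4, seed = 1,
                   control = list(tol = 1e-4))
  expect_s3_class(tf, "emels_tree")
  expect_gte(tf$tree$G, 3)
  sv <- rownames(tf$tree$rpart$splits)
  expect_true(all(sv %in% c("x1", "x2", "x3")))
  # non-decreasing log-likelihood trace up to tolerance
  expect_true(all(diff(tf$trace) > -1e-4 * (abs(tf$trace[-1]) + 1)))
  # leaf-dummy design is exactly the leaf membership matrix
  D <- do.call(rbind, lapply(tf$env$persons, `[[`, "X"))
  expect_true(all(rowSums(D) == 1))
  expect_true(all(D %in% c(0, 1)))
})

test_that("without random effects the alternation reduces to one CART fit", {
  ld <- simulate_tree_data(I = 20, T_len = 20, seed = 46,
                           phi_diag = c(1e-12, 1e-12, 1e-12))
  tf <- emels_tree(y ~ x1 + x2 + x3, ld, model = "lmm_ar1", seed = 1)
  # step-1 residuals equal y itself when b_hat = 0, so the first tree is a
  # plain CART on y; the estimated random intercepts absorb only chance
  # person-mean variation (order sigma/sqrt(T))
  expect_lt(max(abs(tf$eb$tau)), 3 * sqrt(exp(-0.67 + 0.25) / 20))
  d <- as.data.frame(ld)
  ct <- fit_cart(d[c("x1", "x2", "x3")], d$y, seed = 1 + 1)
  expect_equal(ct$G, tf$tree$G)
  expect_equal(sort(unname(ct$leaf_means)), sort(unname(tf$tree$leaf_means)),
               tolerance = 0.05)
})

test_that("a linear mean with small noise yields a stable alternation", {
  # coarse leaves (large minsplit) so the piecewise approximation of the
  # linear trend stabilizes instead of refining indefinitely
  sim <- simulate_emels_data(I = 15, T_len = 20, beta = c(1, 0.8),
                             s0 = -2, r0 = 0, Phi = diag(c(0.3, 1e-8, 1e-8)),
                             seed = 47)
  t2 <- emels_tree(y ~ x1, sim, model = "lmm_ar1", seed = 9, max_alt = 2,
                   minsplit = 60, cp = 0.01)
  tf <- emels_tree(y ~ x1, sim, model = "lmm_ar1", seed = 9, max_alt = 8,
                   minsplit = 60, cp = 0.01)
  expect_lt(abs(tf$logLik - t2$logLik), 2)
  expect_lte(tf$n_alternations, 8)
})
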