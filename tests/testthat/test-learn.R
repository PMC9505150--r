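test_that("ADASYN balances a 30/13 split with exactly 17 synthetic points", {
  set.seed(41)
  x <- matrix(rnorm(43 * 3), 43, 3)
  y <- c(rep(TRUE, 13), rep(FALSE, 30))
  out <- adasyn(x, y, k = 5, beta = 1)
  expect_equal(out$n_synthetic, 17L)
  expect_equal(sum(out$y), 30)
  expect_lte(abs(sum(out$y) - sum(!out$y)), 1)
  # originals preserved verbatim, in order
  expect_identical(out$x[1:43, ], x)
  expect_identical(out$y[1:43], y)
})

test_that("ADASYN leaves balanced input untouched and interpolates minority pairs", {
  set.seed(42)
  x <- matrix(rnorm(40 * 2), 40, 2)
  y <- rep(c(TRUE, FALSE), 20)
  out <- adasyn(x, y)
  expect_identical(out$x, x)
  expect_equal(out$n_synthetic, 0L)

  # every synthetic point lies on a segment between two minority originals
  y2 <- c(rep(TRUE, 6), rep(FALSE, 24))
  x2 <- matrix(rnorm(30 * 2), 30, 2)
  out2 <- adasyn(x2, y2)
  minX <- x2[1:6, ]
  for (r in 31:nrow(out2$x)) {
    p <- out2$x[r, ]
    on_seg <- FALSE
    for (i in 1:5) for (j in (i + 1):6) {
      d <- minX[j, ] - minX[i, ]
      lam <- if (sum(d^2) > 0) sum((p - minX[i, ]) * d) / sum(d^2) else 0
      res <- p - (minX[i, ] + lam * d)
      if (lam >= -1e-9 && lam <= 1 + 1e-9 && sqrt(sum(res^2)) < 1e-9)
        on_seg <- TRUE
    }
    expect_true(on_seg, info = paste("synthetic row", r))
  }

  expect_error(adasyn(x, rep(TRUE, 40)), "both classes")
})

test_that("largest-remainder allocation preserves the total", {
  tgt <- c(3.4, 2.4, 1.2)   # floors 6, total 7
  got <- dosiomics:::largest_remainder(tgt)
  expect_equal(sum(got), 7L)
  expect_equal(got, c(4L, 2L, 1L))
})

test_that("NCA weights respect symmetry, signal and regularization limits", {
  set.seed(7)
  n <- 100
  lab <- runif(n) > 0.5
  sig <- ifelse(lab, 1, 0) + rnorm(n, 0, 0.01)
  # duplicated informative columns end with near-equal weights
  x <- scale(cbind(a = sig, b = sig, noise = rnorm(n)))
  w <- nca_weights(x, lab, seed = 5)
  expect_lt(abs(w["a"] - w["b"]), 0.05)
  expect_gt(w["a"], w["noise"])

  # signal column dominates pure noise
  x2 <- scale(cbind(signal = sig, noise = rnorm(n)))
  w2 <- nca_weights(x2, lab, seed = 6)
  expect_gt(w2["signal"], w2["noise"])

  # enormous regularization kills all weights
  w3 <- nca_weights(x2, lab, lambda = 1000, seed = 7)
  expect_true(all(w3 < 0.01))

  # deterministic given the seed
  expect_identical(nca_weights(x2, lab, seed = 8),
                   nca_weights(x2, lab, seed = 8))
})

test_that("SGD solution is close to the full-batch oracle optimum", {
  set.seed(70)
  n <- 60
  lab <- runif(n) > 0.5
  x <- scale(cbind(ifelse(lab, 1, 0) + rnorm(n, 0, 0.3),
                   rnorm(n), rnorm(n)))
  w_sgd <- nca_weights(x, lab, lambda = 0.02, seed = 3)
  oracle <- nca_batch_oracle(x, lab, lambda = 0.02)
  f_sgd <- nca_objective(x, lab, w_sgd, 0.02)
  expect_gte(f_sgd, oracle$objective - 0.02 * abs(oracle$objective))
  # and the oracle agrees with the package objective evaluation
  expect_equal(nca_objective(x, lab, oracle$w, 0.02),
               nca_objective_oracle(x, lab, oracle$w, 0.02),
               tolerance = 1e-10)
})

test_that("top-weight selection is ordered with deterministic tie-breaks", {
  expect_equal(select_top(c(3, 1, 2), 2), c(1L, 3L))
  expect_equal(sort(select_top(c(3, 1, 2), 3)), 1:3)
  expect_equal(select_top(c(2, 5, 2, 5), 4), c(2L, 4L, 1L, 3L))
  expect_identical(select_top(c(1, 1, 1), 2), c(1L, 2L))
})

test_that("the weak tree solves separable data and respects its split cap", {
  x <- matrix(c(-(10:1), 1:10), ncol = 1)
  y <- rep(c(FALSE, TRUE), each = 10)
  tr <- fit_weak_tree(x, y, max_splits = 4)
  expect_equal(sum(tr$feature >= 0), 1L)          # one split suffices
  expect_equal(as.logical(predict(tr, x, type = "label")), y)

  stump <- fit_weak_tree(x, y, max_splits = 0)
  expect_equal(sum(stump$feature >= 0), 0L)
  # majority class with equal weights and counts: tie scores 0 -> negative
  expect_true(all(predict(stump, x, type = "score") == 0))

  set.seed(91)
  x2 <- matrix(rnorm(20 * 2), 20, 2)
  y2 <- runif(20) > 0.4
  w2 <- runif(20, 0.2, 1)
  tr2 <- fit_weak_tree(x2, y2, w2, max_splits = 4)
  pred <- predict(tr2, x2, type = "label")
  err_tree <- sum(w2[pred != y2]) / sum(w2)
  expect_lte(err_tree, best_stump_error_oracle(x2, y2, w2) + 1e-12)
})

test_that("RobustBoost reaches the error goal on separable data", {
  set.seed(101)
  n <- 200
  x <- matrix(rnorm(n * 2), n, 2)
  y <- x[, 1] + 0.5 * x[, 2] > 0
  fit <- robustboost(x, y, error_goal = 0.05, max_cycles = 500)
  expect_lte(fit$train_error, 0.05)
  expect_lte(fit$n_cycles, 500)
  expect_true(all(is.finite(fit$alphas)))
  # self-time path is strictly increasing
  expect_true(fit$self_time > 0)
})

test_that("one-class input yields a degenerate constant ensemble", {
  x <- matrix(rnorm(20), 10, 2)
  fit <- robustboost(x, rep(TRUE, 10))
  expect_equal(fit$n_cycles, 1L)
  expect_equal(fit$train_error, 0)
  expect_true(all(predict(fit, x, type = "label")))
})

test_that("RobustBoost resists label noise at least as well as AdaBoost", {
  wins <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    set.seed(300 + r)
    n <- 200
    x <- matrix(rnorm(n * 2), n, 2)
    y_true <- x[, 1] + x[, 2] > 0
    y <- y_true
    flip <- sample(n, n %/% 10)
    y[flip] <- !y[flip]
    tr_idx <- 1:140
    te_idx <- 141:200
    # the error goal is set to the known flip rate, the intended use of
    # the robust variant under label noise
    rb <- robustboost(x[tr_idx, ], y[tr_idx], error_goal = 0.10,
                      max_cycles = 300)
    ab <- robustboost(x[tr_idx, ], y[tr_idx], max_cycles = 300,
                      method = "adaboost")
    err_rb <- mean(predict(rb, x[te_idx, ], type = "label") != y[te_idx])
    err_ab <- mean(predict(ab, x[te_idx, ], type = "label") != y[te_idx])
    if (err_rb <= err_ab) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.6)
})

test_that("ensemble prediction is a reproducible weighted vote", {
  set.seed(121)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- x[, 1] > 0
  fit <- robustboost(x, y, max_cycles = 50)
  s1 <- predict(fit, x)
  s2 <- predict(fit, x)
  expect_identical(s1, s2)

  # a single tree with weight 1 scores exactly like the tree's sign
  single <- fit
  single$trees <- fit$trees[1]
  single$alphas <- 1
  s_tree <- tree_sign <- ifelse(
    dosiomics:::tree_predict_cpp(fit$trees[[1]],
      scale(x, center = fit$center, scale = fit$scale)) > 0, 1, -1)
  expect_equal(predict(single, x), as.numeric(s_tree))

  # flipping all vote weights flips all labels (scores are never 0 here)
  flipped <- fit
  flipped$alphas <- -fit$alphas
  sc <- predict(fit, x)
  expect_equal(predict(flipped, x), -sc)
  nonzero <- sc != 0
  expect_equal(predict(flipped, x, type = "label")[nonzero],
               !predict(fit, x, type = "label")[nonzero])

  expect_error(predict(fit, x[, 1:2]), "features")
})
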