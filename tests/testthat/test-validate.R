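test_that("outcome binarization applies the 36-month horizon", {
  expect_true(binarize_outcome(20, TRUE))
  expect_false(binarize_outcome(40, TRUE))     # event beyond horizon
  expect_false(binarize_outcome(12, FALSE))    # censored-early -> negative
  expect_equal(binarize_outcome(c(10, 35, 37, 80),
                                c(TRUE, TRUE, TRUE, FALSE)),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_true(binarize_outcome(40, TRUE, horizon_months = 48))
  expect_error(binarize_outcome(-1, TRUE))
})

test_that("stratified folds partition 43 patients with balanced positives", {
  labels <- c(rep(TRUE, 13), rep(FALSE, 30))
  set.seed(77)
  fold <- make_folds(labels, 10)
  expect_setequal(fold, 1:10)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_true(all(sizes %in% c(4, 5)))
  pos_per_fold <- table(factor(fold[labels], levels = 1:10))
  expect_true(all(pos_per_fold >= 1 & pos_per_fold <= 2))

  set.seed(5); f1 <- make_folds(labels, 10)
  set.seed(5); f2 <- make_folds(labels, 10)
  expect_identical(f1, f2)

  expect_warning(make_folds(c(rep(TRUE, 3), rep(FALSE, 30)), 10),
                 "fewer samples than folds")
  expect_error(make_folds(labels[1:5], 10), "fewer samples")
})

test_that("threshold metrics reproduce contingency arithmetic", {
  scores <- c(rep(1, 3), rep(-1, 1), rep(-1, 6), rep(1, 2))
  labels <- c(rep(TRUE, 4), rep(FALSE, 8))
  m <- classification_metrics(scores, labels)
  expect_equal(unname(m), c(0.75, 0.75, 0.75))

  perfect <- classification_metrics(c(-1, -1, 1, 1),
                                    c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(perfect), c(1, 1, 1))

  allneg <- classification_metrics(rep(-1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(allneg["sensitivity"]), 0)
  expect_equal(unname(allneg["specificity"]), 1)

  expect_error(classification_metrics(1:3, rep(TRUE, 3)), "both classes")
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  for (case in 1:20) {
    set.seed(500 + case)
    n <- sample(8:30, 1)
    scores <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE)  # many ties
    labels <- runif(n) > 0.4
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_pairwise_oracle(scores, labels),
                 tolerance = 1e-12, info = paste("case", case))
  }
  # cross-check against the reference ROC implementation
  set.seed(99)
  sc <- rnorm(60)
  lb <- runif(60) > 0.5
  expect_equal(roc_auc(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("best-m selection maximizes accuracy with ties to smaller m", {
  expect_equal(dosiomics:::pick_best_m(c(0.5, 0.62, 0.60, 0.4)), 2L)
  expect_equal(dosiomics:::pick_best_m(c(0.5, 0.6, 0.6, 0.55)), 2L)
  expect_equal(dosiomics:::pick_best_m(seq(0.1, 0.8, length.out = 8)), 8L)
})

test_that("repeated CV is leakage-safe, deterministic, and self-consistent", {
  # small fabricated feature table with one informative column
  set.seed(1234)
  n <- 40; p <- 15
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- runif(n) < stats::plogis(-0.5 + 2 * x[, 3])
  if (min(table(y)) < 4) y[1:4] <- c(TRUE, TRUE, FALSE, FALSE)
  lc <- learn_config(nca_epochs = 15L, boost_max_cycles = 60L)
  cc <- cv_config(n_folds = 5L, n_repeats = 3L, max_features = 3L,
                  seed = 99L)
  r1 <- run_repeated_cv(x, y, lc, cc)
  r2 <- run_repeated_cv(x, y, lc, cc)
  expect_identical(r1$metrics_rep, r2$metrics_rep)   # end-to-end determinism
  expect_identical(r1$selection_count, r2$selection_count)

  # all metrics live in [0, 1]
  expect_true(all(r1$metrics_rep >= 0 & r1$metrics_rep <= 1))
  expect_true(all(r1$sd >= 0))

  # accuracy = prevalence-weighted mean of sensitivity and specificity
  prev <- mean(y)
  acc_identity <- r1$metrics_rep[, , "sensitivity"] * prev +
    r1$metrics_rep[, , "specificity"] * (1 - prev)
  expect_equal(acc_identity, r1$metrics_rep[, , "accuracy"],
               tolerance = 1e-12, ignore_attr = TRUE)

  # selection tallies: m columns sum to folds x repeats x m
  for (m in 1:3)
    expect_equal(sum(r1$selection_count[, m]), 5L * 3L * m)

  # the informative feature is found
  expect_equal(names(which.max(r1$selection_count[, 1])), "f3")
  expect_gte(r1$mean[r1$m_star, "auc"], 0.6)

  # report utilities
  expect_equal(pick_best(r1), r1$m_star)
  expect_equal(nrow(summary(r1)), 3L)
  expect_output(print(r1), "cv_report")
})

test_that("degenerate feature tables are rejected", {
  x <- matrix(rnorm(30), 10, 3)
  expect_error(run_repeated_cv(x, rep(TRUE, 10)), "2 samples per class")
})
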