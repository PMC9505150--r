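#' Binarize a time-to-event outcome at a horizon
#'
#' Positive iff the failure event occurred no later than `horizon_months`.
#' A patient censored event-free before the horizon is labelled negative —
#' the acknowledged simplification of short-follow-up cohorts, where late
#' relapses are miscategorized as relapse-free.
#'
#' @param time_months positive follow-up / event times.
#' @param event logical event indicators.
#' @param horizon_months classification horizon (default 36).
#' @return Logical labels, `TRUE` = local failure within the horizon.
#' @export
binarize_outcome <- function(time_months, event, horizon_months = 36) {
  stopifnot(all(time_months > 0))
  as.logical(event) & time_months <= horizon_months
}

#' Stratified cross-validation folds
#'
#' Partitions samples into `n_folds` folds with sizes differing by at most
#' one, stratified by class so each fold receives its share of positives.
#' A class smaller than the fold count degrades gracefully (some folds get
#' none) with a warning.
#'
#' @param labels logical class labels.
#' @param n_folds fold count (default 10).
#' @param stratified stratify by class (default TRUE).
#' @return Integer fold assignment, values in `1..n_folds`.
#' @export
make_folds <- function(labels, n_folds = 10L, stratified = TRUE) {
  n <- length(labels)
  if (n < n_folds) stop("fewer samples than folds", call. = FALSE)
  fold <- integer(n)
  if (stratified) {
    if (min(table(labels)) < n_folds)
      warning("a class has fewer samples than folds: ",
              "stratification is partial")
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(n_folds), length(idx))
    }
  } else {
    fold <- rep_len(sample.int(n_folds), n)[sample.int(n)]
  }
  fold
}

#' Threshold classification metrics
#'
#' Sensitivity (true-positive rate), specificity (true-negative rate) and
#' accuracy of scores thresholded at `threshold` (ties to negative).
#'
#' @param scores numeric classifier scores.
#' @param labels logical labels.
#' @param threshold decision threshold (default 0, the ensemble's natural
#'   vote threshold).
#' @return Named vector `(sensitivity, specificity, accuracy)`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("metrics need both classes present", call. = FALSE)
  pred <- scores > threshold
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(labels))
}

#' ROC curve and AUC
#'
#' Trapezoidal area under the ROC curve over all score thresholds, equal
#' to the normalized Mann-Whitney U statistic with ties counted one half.
#'
#' @inheritParams classification_metrics
#' @return List with `auc` and a `curve` data frame (fpr, tpr, threshold).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("ROC needs both classes present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # collapse tied scores into single thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(l))
  fpr <- c(0, fp[last] / sum(!l))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(auc = auc,
       curve = data.frame(fpr = fpr, tpr = tpr,
                          threshold = c(Inf, s[last])))
}

#' Cross-validation configuration
#'
#' @param n_folds folds per repetition (default 10).
#' @param n_repeats repetitions (default 100).
#' @param max_features largest selected-feature count swept (default 8).
#' @param stratified stratified folds (default TRUE).
#' @param seed master seed.
#' @return List of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, n_repeats = 100L, max_features = 8L,
                      stratified = TRUE, seed = 1L) {
  stopifnot(n_folds >= 2, max_features >= 1, n_repeats >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 max_features = as.integer(max_features),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_config")
}

#' Learning-stack configuration
#'
#' Hyperparameters of the in-fold pipeline: ADASYN neighbour count and
#' balance ratio, NCA regularization and SGD schedule, RobustBoost error
#' goal / cycle cap / tree depth, and whether NCA sees the oversampled or
#' the raw training fold.
#'
#' @param adasyn_k,adasyn_beta ADASYN neighbours (5) and balance (1).
#' @param nca_lambda NCA regularization (0.02).
#' @param nca_epochs,nca_lr0,nca_decay NCA SGD schedule.
#' @param boost_error_goal RobustBoost error target (0.05).
#' @param boost_max_cycles learning-cycle cap (500).
#' @param tree_max_splits weak-tree split cap (4).
#' @param nca_on_augmented run NCA on the ADASYN-augmented fold (TRUE).
#' @param boost_method `"robustboost"` or `"adaboost"`.
#' @return List of class `learn_config`.
#' @export
learn_config <- function(adasyn_k = 5L, adasyn_beta = 1,
                         nca_lambda = 0.02, nca_epochs = 50L,
                         nca_lr0 = 0.5, nca_decay = 0.2,
                         boost_error_goal = 0.05, boost_max_cycles = 500L,
                         tree_max_splits = 4L, nca_on_augmented = TRUE,
                         boost_method = "robustboost") {
  stopifnot(adasyn_k >= 1, adasyn_beta > 0, adasyn_beta <= 1,
            boost_error_goal > 0, boost_error_goal < 0.5)
  structure(list(adasyn_k = as.integer(adasyn_k), adasyn_beta = adasyn_beta,
                 nca_lambda = nca_lambda, nca_epochs = as.integer(nca_epochs),
                 nca_lr0 = nca_lr0, nca_decay = nca_decay,
                 boost_error_goal = boost_error_goal,
                 boost_max_cycles = as.integer(boost_max_cycles),
                 tree_max_splits = as.integer(tree_max_splits),
                 nca_on_augmented = isTRUE(nca_on_augmented),
                 boost_method = boost_method),
            class = "learn_config")
}

#' Repeated leakage-safe cross-validation over feature counts
#'
#' For every repetition and fold: standardize on the training fold only,
#' oversample the training minority with ADASYN, learn NCA feature weights
#' on the (augmented) training fold, and for each feature count
#' `m = 1..max_features` fit a RobustBoost ensemble on the top-m features
#' and score the untouched test fold. Per repetition the test folds are
#' pooled into one prediction per patient and sensitivity, specificity,
#' accuracy and AUC computed; means and SDs are reported over repetitions.
#' A runtime guard asserts train/test disjointness in every fold; folds
#' whose training split loses a class are re-drawn (logged).
#'
#' @param features feature table: data frame or matrix of numeric
#'   features (non-feature columns `patient_id`, `event`, `time_months`
#'   are dropped automatically).
#' @param labels logical outcome labels.
#' @param learn a [learn_config()].
#' @param cv a [cv_config()].
#' @return A `cv_report`: per-m metric means/SDs, the selection-frequency
#'   table, pooled ROC points at the accuracy-best `m_star`, and the
#'   per-repetition metric draws.
#' @export
run_repeated_cv <- function(features, labels, learn = learn_config(),
                            cv = cv_config()) {
  meta_cols <- c("patient_id", "event", "time_months")
  if (is.data.frame(features))
    features <- features[, setdiff(colnames(features), meta_cols)]
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  labels <- as.logical(labels)
  n <- nrow(x)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cv$seed)

  M <- cv$max_features
  metrics_rep <- array(NA_real_,
                       c(cv$n_repeats, M, 4),
                       dimnames = list(NULL, NULL,
                                       c("sensitivity", "specificity",
                                         "accuracy", "auc")))
  sel_count <- matrix(0L, ncol(x), M,
                      dimnames = list(colnames(x), NULL))
  scores_all <- array(NA_real_, c(cv$n_repeats, M, n))
  redraws <- 0L

  for (rep_i in seq_len(cv$n_repeats)) {
    for (attempt in 1:10) {
      fold <- make_folds(labels, cv$n_folds, cv$stratified)
      ok <- all(vapply(seq_len(cv$n_folds), function(f)
        length(unique(labels[fold != f])) == 2L, TRUE))
      if (ok) break
      redraws <- redraws + 1L
    }
    for (f in seq_len(cv$n_folds)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      stopifnot(length(intersect(tr, te)) == 0L)  # leakage guard
      ctr <- colMeans(x[tr, , drop = FALSE])
      scl <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      scl[!is.finite(scl) | scl == 0] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, ctr), 2, scl, "/")
      xte <- sweep(sweep(x[te, , drop = FALSE], 2, ctr), 2, scl, "/")
      aug <- adasyn(xtr, labels[tr], k = learn$adasyn_k,
                    beta = learn$adasyn_beta)
      wsrc <- if (learn$nca_on_augmented) aug else
        list(x = xtr, y = labels[tr])
      w <- nca_weights(wsrc$x, wsrc$y, lambda = learn$nca_lambda,
                       epochs = learn$nca_epochs, lr0 = learn$nca_lr0,
                       decay = learn$nca_decay,
                       seed = sample.int(.Machine$integer.max, 1L))
      for (m in seq_len(M)) {
        sel <- select_top(w, m)
        sel_count[sel, m] <- sel_count[sel, m] + 1L
        fit <- robustboost(aug$x[, sel, drop = FALSE], aug$y,
                           error_goal = learn$boost_error_goal,
                           max_cycles = learn$boost_max_cycles,
                           max_splits = learn$tree_max_splits,
                           method = learn$boost_method,
                           standardize = FALSE)
        scores_all[rep_i, m, te] <-
          predict(fit, xte[, sel, drop = FALSE], type = "score")
      }
    }
    for (m in seq_len(M)) {
      sc <- scores_all[rep_i, m, ]
      metrics_rep[rep_i, m, 1:3] <- classification_metrics(sc, labels)
      metrics_rep[rep_i, m, 4] <- roc_auc(sc, labels)$auc
    }
  }

  mean_m <- apply(metrics_rep, c(2, 3), mean)
  sd_m <- apply(metrics_rep, c(2, 3), stats::sd)
  m_star <- pick_best_m(mean_m[, "accuracy"])
  sc_star <- matrix(scores_all[, m_star, ], nrow = cv$n_repeats)
  pooled <- roc_auc(as.vector(t(sc_star)), rep(labels, times = cv$n_repeats))
  freq <- sort(sel_count[, m_star][sel_count[, m_star] > 0],
               decreasing = TRUE)
  structure(list(mean = mean_m, sd = sd_m, m_star = m_star,
                 metrics_rep = metrics_rep,
                 selection_count = sel_count,
                 selection_frequency = freq,
                 roc = pooled$curve,
                 pooled_auc = pooled$auc,
                 labels = labels, n_redraws = redraws,
                 cv = cv, learn = learn),
            class = "cv_report")
}

pick_best_m <- function(acc) which.max(acc)   # ties: which.max takes first

#' Best feature count of a CV report
#'
#' The feature count with the highest mean accuracy; ties favour the
#' smaller model.
#'
#' @param report a `cv_report`.
#' @return Integer `m_star`.
#' @export
pick_best <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  report$m_star
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d x %d-fold CV over m = 1..%d features\n",
              x$cv$n_repeats, x$cv$n_folds, x$cv$max_features))
  m <- x$m_star
  cat(sprintf("  best m* = %d (by mean accuracy)\n", m))
  cat(sprintf("  AUC %.2f (+/- %.2f), sens %.2f (+/- %.2f), spec %.2f (+/- %.2f), acc %.2f (+/- %.2f)\n",
              x$mean[m, "auc"], x$sd[m, "auc"],
              x$mean[m, "sensitivity"], x$sd[m, "sensitivity"],
              x$mean[m, "specificity"], x$sd[m, "specificity"],
              x$mean[m, "accuracy"], x$sd[m, "accuracy"]))
  top <- utils::head(x$selection_frequency, 5)
  cat("  most selected:", paste(names(top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  tab <- data.frame(m = seq_len(nrow(object$mean)),
                    auc = object$mean[, "auc"], auc_sd = object$sd[, "auc"],
                    sensitivity = object$mean[, "sensitivity"],
                    specificity = object$mean[, "specificity"],
                    accuracy = object$mean[, "accuracy"],
                    accuracy_sd = object$sd[, "accuracy"])
  rownames(tab) <- NULL
  tab
}

#' Diagnostic plots of a CV report
#'
#' `which = "metrics"`: mean metrics against feature count;
#' `"roc"`: pooled ROC at the best feature count; `"frequency"`: the most
#' frequently selected features.
#'
#' @param x a `cv_report`.
#' @param which one of `"metrics"`, `"roc"`, `"frequency"`.
#' @param top_n features shown in the frequency plot.
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.cv_report <- function(x, which = c("metrics", "roc", "frequency"),
                           top_n = 10, ...) {
  which <- match.arg(which)
  if (which == "metrics") {
    matplot(seq_len(nrow(x$mean)), x$mean, type = "b", pch = 1:4,
            lty = 1, xlab = "number of selected features",
            ylab = "mean CV metric", ylim = c(0, 1), ...)
    abline(v = x$m_star, lty = 3)
    legend("bottomright", colnames(x$mean), pch = 1:4, lty = 1,
           col = 1:4, bty = "n")
  } else if (which == "roc") {
    plot(x$roc$fpr, x$roc$tpr, type = "l",
         xlab = "1 - specificity", ylab = "sensitivity",
         main = sprintf("pooled ROC, m* = %d (AUC %.2f)", x$m_star,
                        x$pooled_auc), ...)
    abline(0, 1, lty = 3)
  } else {
    top <- utils::head(x$selection_frequency, top_n)
    op <- par(mar = c(5, 12, 2, 1))
    on.exit(par(op))
    barplot(rev(top), horiz = TRUE, las = 1,
            xlab = sprintf("selections over %d folds x %d repeats",
                           x$cv$n_folds, x$cv$n_repeats), ...)
  }
  invisible(x)
}
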