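#' RobustBoost ensemble of shallow decision trees
#'
#' Fits a boosting-by-majority ensemble designed to tolerate label noise.
#' Each example carries a real-valued margin; the algorithm runs in
#' self-time \eqn{t \in [0, 1]} and weighs examples by a Gaussian
#' potential centred on a time-dependent target margin, so examples that
#' are hopelessly misclassified stop dominating the weights (the failure
#' mode of AdaBoost under label noise). Each cycle fits a weighted CART
#' tree with at most `max_splits` internal splits, then solves jointly for
#' the time step and vote weight that zero the weighted correlation while
#' conserving the average potential; boosting stops when self-time reaches
#' 1 or after `max_cycles` cycles. The error goal (default 5%) sets the
#' fraction of training margins allowed below the target margin.
#'
#' Features are standardized internally on the training data and the
#' parameters stored, so prediction applies the training-fold scaling.
#'
#' @param x numeric feature matrix.
#' @param y labels: logical, 0/1 or a 2-level factor; the positive class
#'   scores positively.
#' @param error_goal target training classification error in (0, 0.5).
#' @param max_cycles maximum boosting cycles (default 500).
#' @param max_splits maximum internal splits per weak tree (default 4).
#' @param sigma_f final margin spread of the potential (default 0.1).
#' @param theta target margin (default 0).
#' @param method `"robustboost"` (default) or `"adaboost"`, the classical
#'   comparator behind the same interface.
#' @param standardize z-score features on the training data (default
#'   TRUE).
#' @return An object of class `robustboost` with `print`, `predict` and
#'   `coef` methods.
#' @export
robustboost <- function(x, y, error_goal = 0.05, max_cycles = 500L,
                        max_splits = 4L, sigma_f = 0.1, theta = 0,
                        method = c("robustboost", "adaboost"),
                        standardize = TRUE) {
  method <- match.arg(method)
  stopifnot(error_goal > 0, error_goal < 0.5, max_cycles >= 1)
  x <- as.matrix(x)
  yl <- as_binary_labels(y)
  n <- nrow(x)
  if (length(yl) != n) stop("length(y) must match nrow(x)", call. = FALSE)

  ctr <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (standardize) apply(x, 2, stats::sd) else rep(1, ncol(x))
  scl[!is.finite(scl) | scl == 0] <- 1    # constant feature: leave centred
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  ypm <- ifelse(yl, 1L, -1L)
  if (length(unique(yl)) < 2L) {
    # one-class input: degenerate single-leaf ensemble
    fit <- list(trees = list(list(feature = -1L, threshold = 0,
                                  left = -1L, right = -1L,
                                  score = if (yl[1]) 1 else -1)),
                alphas = 1, n_cycles = 1L, self_time = 1, hit_time = TRUE)
  } else if (method == "robustboost") {
    fit <- robustboost_cpp(xs, ypm, error_goal, sigma_f, theta,
                           as.integer(max_cycles), as.integer(max_splits))
    if (!length(fit$trees))
      stop("boosting produced no usable weak learner", call. = FALSE)
    if (!fit$hit_time && fit$n_cycles < max_cycles)
      warning("self-time root search stalled at t = ",
              signif(fit$self_time, 3), "; returning the ", fit$n_cycles,
              "-cycle ensemble")
  } else {
    fit <- adaboost_cpp(xs, ypm, as.integer(max_cycles),
                        as.integer(max_splits))
    if (!length(fit$trees))
      stop("boosting produced no usable weak learner", call. = FALSE)
  }
  scores <- ensemble_score_cpp(fit$trees, fit$alphas, xs)
  structure(list(trees = fit$trees, alphas = as.numeric(fit$alphas),
                 method = method, center = ctr, scale = scl,
                 feature_names = colnames(x),
                 n_cycles = length(fit$trees),
                 self_time = fit$self_time,
                 error_goal = error_goal,
                 train_error = mean((scores > 0) != yl),
                 levels = attr(yl, "levels")),
            class = "robustboost")
}

as_binary_labels <- function(y) {
  if (is.logical(y)) {
    out <- y
    attr(out, "levels") <- c("FALSE", "TRUE")
  } else if (is.factor(y)) {
    if (nlevels(y) > 2L) stop("y must be binary", call. = FALSE)
    out <- as.integer(y) == 2L
    attr(out, "levels") <- levels(y)
  } else {
    u <- sort(unique(y))
    if (!all(y %in% c(0, 1))) stop("numeric y must be 0/1", call. = FALSE)
    out <- y == 1
    attr(out, "levels") <- c("0", "1")
  }
  out
}

#' @export
print.robustboost <- function(x, ...) {
  cat(sprintf("<%s ensemble> %d weak trees", x$method, x$n_cycles))
  if (x$method == "robustboost")
    cat(sprintf(", self-time %.3f, error goal %.0f%%",
                x$self_time, 100 * x$error_goal))
  cat(sprintf("\n  training error %.3f on %d features\n",
              x$train_error, length(x$center)))
  invisible(x)
}

#' @export
coef.robustboost <- function(object, ...) object$alphas

#' Predict from a boosted ensemble
#'
#' `type = "score"` returns the weighted vote
#' \eqn{\sum_k \alpha_k h_k(x)} (positive favours the positive class);
#' `type = "label"` thresholds at 0 with ties to the negative class.
#' The stored training-fold standardization is applied first.
#'
#' @param object a [robustboost()] model.
#' @param newdata feature matrix with the model's features.
#' @param type `"score"` or `"label"`.
#' @param ... unused.
#' @return Numeric scores or logical labels.
#' @export
predict.robustboost <- function(object, newdata,
                                type = c("score", "label"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(object$feature_names) || is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$center))
      stop("newdata lacks the model's features", call. = FALSE)
  } else {
    miss <- setdiff(object$feature_names, colnames(newdata))
    if (length(miss))
      stop("newdata lacks the model's features: ",
           paste(miss, collapse = ", "), call. = FALSE)
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  s <- ensemble_score_cpp(object$trees, object$alphas, xs)
  if (type == "score") s else s > 0
}

#' Fit a single weighted weak tree
#'
#' Best-first weighted-Gini CART with at most `max_splits` internal
#' splits, the weak learner used inside [robustboost()]. Exposed for
#' inspection and testing.
#'
#' @param x feature matrix.
#' @param y binary labels.
#' @param weights non-negative observation weights, not all zero.
#' @param max_splits maximum internal splits.
#' @return A list of class `weak_tree` (`predict` returns leaf scores).
#' @export
fit_weak_tree <- function(x, y, weights = NULL, max_splits = 4L) {
  x <- as.matrix(x)
  yl <- as_binary_labels(y)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero", call. = FALSE)
  tr <- tree_fit_cpp(x, ifelse(yl, 1L, -1L), weights,
                     as.integer(max_splits))
  structure(tr, class = "weak_tree")
}

#' @export
predict.weak_tree <- function(object, newdata,
                              type = c("score", "label"), ...) {
  type <- match.arg(type)
  s <- tree_predict_cpp(unclass(object), as.matrix(newdata))
  if (type == "score") s else s > 0
}

#' @export
print.weak_tree <- function(x, ...) {
  cat(sprintf("<weak_tree> %d internal splits, %d leaves\n",
              sum(x$feature >= 0), sum(x$feature < 0)))
  invisible(x)
}
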