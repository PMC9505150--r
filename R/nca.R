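#' Neighbourhood component analysis feature weights
#'
#' Learns non-negative per-feature weights by maximizing the regularized
#' expected leave-one-out nearest-neighbour accuracy
#' \deqn{F(w) = \frac{1}{n}\sum_i p_i - \lambda \sum_r w_r^2,\qquad
#'       p_i = \sum_{j \ne i,\, y_j = y_i} p_{ij},}
#' where \eqn{p_{ij} \propto \exp(-\sum_r w_r^2 |x_{ir} - x_{jr}|)} is the
#' soft-neighbour probability under the weighted L1 metric. Solved by
#' per-sample stochastic gradient ascent with a `1/(1 + decay * epoch)`
#' learning-rate schedule; deterministic given `seed`. Irrelevant features
#' are driven towards zero by the regularizer (default
#' `lambda = 0.02`). Features should be standardized beforehand.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y class labels (any type; compared by equality).
#' @param lambda regularization strength (default 0.02).
#' @param epochs SGD epochs (default 50).
#' @param lr0,decay learning-rate schedule parameters.
#' @param seed integer seed for the SGD shuffling.
#' @return Numeric vector of non-negative feature weights (named when `x`
#'   has column names).
#' @export
nca_weights <- function(x, y, lambda = 0.02, epochs = 50L, lr0 = 0.5,
                        decay = 0.2, seed = 1L) {
  x <- as.matrix(x)
  yi <- as.integer(factor(y))
  if (length(unique(yi)) < 2L || min(table(yi)) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  w <- nca_sgd_cpp(x, yi, lambda, as.integer(epochs), lr0, decay,
                   as.integer(seed))
  if (any(!is.finite(w)))
    stop("NCA diverged to non-finite weights; reduce `lr0`", call. = FALSE)
  names(w) <- colnames(x)
  w
}

#' Objective value of the NCA criterion
#'
#' @inheritParams nca_weights
#' @param w weight vector.
#' @return Scalar objective \eqn{F(w)}.
#' @export
nca_objective <- function(x, y, w, lambda = 0.02) {
  nca_objective_cpp(as.matrix(x), as.integer(factor(y)), as.numeric(w),
                    lambda)
}

#' Select the top-weighted features
#'
#' Indices of the `m` largest weights in descending weight order, ties
#' broken by catalogue (column) order so selection is deterministic.
#'
#' @param weights numeric weights.
#' @param m number of features to keep.
#' @return Integer vector of feature indices, length `m`.
#' @export
select_top <- function(weights, m) {
  stopifnot(m >= 1, m <= length(weights))
  order(-weights, seq_along(weights))[seq_len(m)]
}
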