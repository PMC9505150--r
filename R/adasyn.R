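#' ADASYN adaptive synthetic oversampling
#'
#' Synthesizes minority-class samples preferentially near the class
#' boundary. With majority count `n_maj` and minority count `n_min`,
#' `G = round((n_maj - n_min) * beta)` synthetic points are allocated over
#' the minority points proportionally to the fraction of majority samples
#' among each point's `k` nearest neighbours (largest-remainder rounding
#' so the allocations sum exactly to `G`). Each synthetic point is a
#' uniform convex combination `x_i + lambda * (x_z - x_i)` of a minority
#' point and one of its minority k-nearest neighbours. Original rows are
#' preserved verbatim. Expects standardized features (Euclidean k-NN).
#'
#' @param x numeric feature matrix.
#' @param y logical or 0/1 labels; `TRUE`/1 is the positive class.
#' @param k neighbour count (default 5).
#' @param beta target balance ratio in (0, 1] (default 1: full balance).
#' @return List with augmented `x`, `y`, and `n_synthetic`.
#' @export
adasyn <- function(x, y, k = 5L, beta = 1) {
  x <- as.matrix(x)
  y <- as.logical(y)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  n_pos <- sum(y); n_neg <- sum(!y)
  minority <- n_pos <= n_neg
  n_min <- min(n_pos, n_neg); n_maj <- max(n_pos, n_neg)
  if (n_min < 2L) stop("need at least 2 minority samples", call. = FALSE)
  G <- round((n_maj - n_min) * beta)
  if (G == 0)
    return(list(x = x, y = y, n_synthetic = 0L))

  min_idx <- which(y == minority)
  d2 <- dist2_pairwise(x)
  diag(d2) <- Inf
  kk <- min(k, nrow(x) - 1L)
  # fraction of majority samples among each minority point's k-NN
  r <- vapply(min_idx, function(i) {
    nb <- order(d2[i, ])[seq_len(kk)]
    sum(y[nb] != minority) / kk
  }, 0)
  if (sum(r) == 0) {
    warning("minority class isolated from majority: uniform allocation")
    r <- rep(1, length(min_idx))
  }
  g <- largest_remainder(r / sum(r) * G)

  kmin <- min(k, n_min - 1L)
  synth <- matrix(NA_real_, G, ncol(x))
  row <- 0L
  for (j in seq_along(min_idx)) {
    if (g[j] == 0) next
    i <- min_idx[j]
    nb_min <- min_idx[min_idx != i]
    nb_min <- nb_min[order(d2[i, nb_min])][seq_len(kmin)]
    for (s in seq_len(g[j])) {
      z <- nb_min[sample.int(length(nb_min), 1L)]
      lam <- runif(1)
      row <- row + 1L
      synth[row, ] <- x[i, ] + lam * (x[z, ] - x[i, ])
    }
  }
  colnames(synth) <- colnames(x)
  list(x = rbind(x, synth), y = c(y, rep(minority, G)),
       n_synthetic = as.integer(G))
}

# integer allocation preserving the total: floor everything, then hand the
# remaining units to the largest fractional parts (ties to earlier index)
largest_remainder <- function(target) {
  fl <- floor(target)
  rem <- round(sum(target)) - sum(fl)
  if (rem > 0) {
    extra <- order(target - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}
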