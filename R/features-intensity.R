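#' Intensity-based statistical features
#'
#' Eighteen first-order statistics of the non-missing ROI intensities.
#' Variance is the population form (divide by N); skewness and kurtosis
#' follow the moment definitions with excess (Fisher) kurtosis, both set
#' to 0 for a constant ROI. "Robust MAD" restricts the mean absolute
#' deviation to values within the 10th-90th percentile band; "median AD"
#' is the mean absolute deviation from the median.
#'
#' @param masked an [image_volume()] with `NA` outside the ROI, or a
#'   numeric vector of ROI intensities.
#' @return Named numeric vector of length 18 (prefix `stat_`).
#' @export
intensity_statistics <- function(masked) {
  x <- roi_values(masked)
  if (!length(x)) stop("empty ROI", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  sdev <- sqrt(v)
  skew <- if (v > 0) mean((x - mu)^3) / sdev^3 else 0
  kurt <- if (v > 0) mean((x - mu)^4) / v^2 - 3 else 0
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  inband <- x[x >= q[1] & x <= q[5]]
  c(stat_mean = mu,
    stat_variance = v,
    stat_skewness = skew,
    stat_kurtosis = kurt,
    stat_median = q[3],
    stat_min = min(x),
    stat_p10 = q[1],
    stat_p90 = q[5],
    stat_max = max(x),
    stat_iqr = q[4] - q[2],
    stat_range = max(x) - min(x),
    stat_mad = mean(abs(x - mu)),
    stat_robust_mad = mean(abs(inband - mean(inband))),
    stat_median_ad = mean(abs(x - q[3])),
    stat_cov = if (mu != 0) sdev / mu else 0,
    stat_qcod = if (q[4] + q[2] != 0) (q[4] - q[2]) / (q[4] + q[2]) else 0,
    stat_energy = sum(x^2),
    stat_rms = sqrt(mean(x^2)))
}

#' Integrated intensity
#'
#' Mean ROI intensity multiplied by the ROI voxel volume in mm^3 — for a
#' BED distribution, the average dose in the target scaled by its volume.
#'
#' @param masked an [image_volume()] with `NA` outside the ROI.
#' @param mask the matching [roi_mask()].
#' @param spacing_mm voxel spacing (defaults to the volume's).
#' @return A single named value `integrated_intensity`.
#' @export
integrated_intensity <- function(masked, mask, spacing_mm = NULL) {
  x <- roi_values(masked)
  if (!length(x)) stop("empty ROI", call. = FALSE)
  if (is.null(spacing_mm))
    spacing_mm <- if (inherits(masked, "image_volume")) masked$spacing_mm
                  else mask$spacing_mm
  vol <- sum(mask$values >= 0.5) * prod(spacing_mm)
  c(integrated_intensity = mean(x) * vol)
}

#' Intensity-histogram features
#'
#' Twenty-three statistics of the discretized grey levels inside the ROI,
#' computed on the full 1..`n_levels` histogram: moments, order statistics,
#' dispersion measures, mode (lowest level on ties), entropy (log2),
#' uniformity, and the extrema of the histogram gradient with the levels
#' at which they occur (central differences, one-sided at the ends).
#'
#' @param discretized an [image_volume()] of grey levels with `NA` outside
#'   the ROI (as produced by [discretize_fbn()]), or an integer vector.
#' @param n_levels number of grey levels; taken from the volume's
#'   `n_levels` attribute when present.
#' @return Named numeric vector of length 23 (prefix `hist_`).
#' @export
histogram_features <- function(discretized, n_levels = NULL) {
  if (is.null(n_levels)) n_levels <- attr(discretized, "n_levels")
  if (is.null(n_levels)) n_levels <- 64L
  g <- roi_values(discretized)
  if (!length(g)) stop("empty ROI", call. = FALSE)
  if (any(g < 1 | g > n_levels))
    stop("grey levels outside 1..n_levels", call. = FALSE)
  n <- length(g)
  counts <- tabulate(g, nbins = n_levels)
  p <- counts / n
  mu <- mean(g)
  v <- mean((g - mu)^2)
  sdev <- sqrt(v)
  skew <- if (v > 0) mean((g - mu)^3) / sdev^3 else 0
  kurt <- if (v > 0) mean((g - mu)^4) / v^2 - 3 else 0
  q <- stats::quantile(g, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  inband <- g[g >= q[1] & g <= q[5]]
  nz <- p[p > 0]
  grad <- histogram_gradient(counts)
  c(hist_mean = mu,
    hist_variance = v,
    hist_skewness = skew,
    hist_kurtosis = kurt,
    hist_median = q[3],
    hist_min = min(g),
    hist_p10 = q[1],
    hist_p90 = q[5],
    hist_max = max(g),
    hist_mode = which.max(counts),
    hist_iqr = q[4] - q[2],
    hist_range = max(g) - min(g),
    hist_mad = mean(abs(g - mu)),
    hist_robust_mad = mean(abs(inband - mean(inband))),
    hist_median_ad = mean(abs(g - q[3])),
    hist_cov = if (mu != 0) sdev / mu else 0,
    hist_qcod = if (q[4] + q[2] != 0) (q[4] - q[2]) / (q[4] + q[2]) else 0,
    hist_entropy = -sum(nz * log2(nz)),
    hist_uniformity = sum(nz^2),
    hist_max_gradient = max(grad),
    hist_max_gradient_level = which.max(grad),
    hist_min_gradient = min(grad),
    hist_min_gradient_level = which.min(grad))
}

histogram_gradient <- function(counts) {
  n <- length(counts)
  if (n == 1) return(0)
  g <- numeric(n)
  g[1] <- counts[2] - counts[1]
  g[n] <- counts[n] - counts[n - 1]
  if (n > 2) g[2:(n - 1)] <- (counts[3:n] - counts[1:(n - 2)]) / 2
  g
}

# extract the non-missing voxel values of a masked volume (or pass a
# plain vector through)
roi_values <- function(x) {
  v <- if (inherits(x, "image_volume")) x$values else x
  as.vector(v[!is.na(v)])
}
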