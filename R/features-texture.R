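#' Texture-matrix features (GLCM, GLRLM, GLSZM, NGTDM, NGLDM)
#'
#' Texture features of a discretized ROI following the conventions of the
#' image biomarker standardization effort: 3D matrices at Chebyshev
#' distance 1, grey-level co-occurrence and run-length matrices built per
#' direction over the 13 unique 3D directions and features averaged over
#' directions, size-zone and dependence matrices on the 26-connected
#' neighbourhood (dependence coarseness alpha = 0), neighbourhood
#' grey-tone difference on the full 26-neighbourhood. Matrices are built
#' only from non-missing voxel pairs/neighbourhoods, so the ROI boundary
#' contributes no phantom pairs.
#'
#' @param discretized an [image_volume()] of grey levels 1..`n_levels`
#'   with `NA` outside the ROI (see [discretize_fbn()]).
#' @param mask optional [roi_mask()]; when given, voxels outside are
#'   treated as missing.
#' @param n_levels number of grey levels (from the `n_levels` attribute
#'   by default).
#' @return Named numeric vector (`glcm_` 25, `glrlm_` 16, `glszm_` 16,
#'   `ngtdm_` 5, `ngldm_` 17 values respectively).
#' @name texture_features
NULL

texture_levels <- function(discretized, mask = NULL, n_levels = NULL) {
  if (is.null(n_levels)) n_levels <- attr(discretized, "n_levels")
  if (is.null(n_levels)) n_levels <- 64L
  v <- if (inherits(discretized, "image_volume")) discretized$values
       else discretized
  if (!is.null(mask)) v[mask$values < 0.5] <- NA
  if (sum(!is.na(v)) < 2) stop("need at least 2 ROI voxels", call. = FALSE)
  lev <- array(0L, dim(v))
  lev[!is.na(v)] <- as.integer(v[!is.na(v)])
  if (any(lev < 0L) || any(lev > n_levels))
    stop("grey levels outside 1..n_levels", call. = FALSE)
  list(levels = lev, n_levels = as.integer(n_levels),
       n_voxels = sum(lev > 0L))
}

# cache of the C++ matrix pass keyed on the array; computed per call site
texture_matrices <- function(discretized, mask = NULL, n_levels = NULL) {
  tl <- texture_levels(discretized, mask, n_levels)
  tm <- texture_matrices_cpp(tl$levels, tl$n_levels)
  tm$n_levels <- tl$n_levels
  tm$n_voxels <- tl$n_voxels
  tm
}

#' @rdname texture_features
#' @export
glcm_features <- function(discretized, mask = NULL, n_levels = NULL) {
  tm <- texture_matrices(discretized, mask, n_levels)
  glcm_features_from_matrices(tm$glcm)
}

glcm_features_from_matrices <- function(glcm) {
  nd <- dim(glcm)[3]
  acc <- NULL
  used <- 0
  for (d in seq_len(nd)) {
    M <- glcm[, , d]
    s <- sum(M)
    if (s == 0) next          # thin ROI: no valid pairs along this direction
    f <- glcm_features_one(M / s)
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1
  }
  if (used == 0) stop("no valid co-occurrence pairs in any direction",
                      call. = FALSE)
  acc / used
}

glcm_features_one <- function(p) {
  N <- nrow(p)
  i <- matrix(seq_len(N), N, N)
  j <- t(i)
  px <- rowSums(p)                  # symmetric matrix: px == py
  mu_x <- sum(seq_len(N) * px)
  var_x <- sum((seq_len(N) - mu_x)^2 * px)
  mu <- sum(i * p)
  pd <- vapply(0:(N - 1), function(k) sum(p[abs(i - j) == k]), 0)  # |i-j|
  ps <- vapply(2:(2 * N), function(k) sum(p[i + j == k]), 0)       # i+j
  kd <- 0:(N - 1)
  ks <- 2:(2 * N)
  da <- sum(kd * pd)
  sa <- sum(ks * ps)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(p)
  pxpy <- outer(px, px)
  hxy1 <- -sum((p * log2(pxpy))[p > 0 & pxpy > 0])
  hxy2 <- ent(pxpy)
  hx <- ent(px)
  corr <- if (var_x > 0) (sum(i * j * p) - mu_x^2) / var_x else 1
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  c(glcm_joint_max = max(p),
    glcm_joint_average = mu,
    glcm_joint_variance = sum((i - mu)^2 * p),
    glcm_joint_entropy = hxy,
    glcm_diff_average = da,
    glcm_diff_variance = sum((kd - da)^2 * pd),
    glcm_diff_entropy = ent(pd),
    glcm_sum_average = sa,
    glcm_sum_variance = sum((ks - sa)^2 * ps),
    glcm_sum_entropy = ent(ps),
    glcm_energy = sum(p^2),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_dissimilarity = sum(abs(i - j) * p),
    glcm_inverse_difference = sum(p / (1 + abs(i - j))),
    glcm_inverse_difference_norm = sum(p / (1 + abs(i - j) / N)),
    glcm_inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    glcm_inverse_difference_moment_norm = sum(p / (1 + (i - j)^2 / N^2)),
    glcm_inverse_variance = sum((p / (i - j)^2)[i != j]),
    glcm_correlation = corr,
    glcm_autocorrelation = sum(i * j * p),
    glcm_cluster_tendency = sum((i + j - 2 * mu_x)^2 * p),
    glcm_cluster_shade = sum((i + j - 2 * mu_x)^3 * p),
    glcm_cluster_prominence = sum((i + j - 2 * mu_x)^4 * p),
    glcm_info_corr1 = ic1,
    glcm_info_corr2 = ic2)
}

#' @rdname texture_features
#' @export
glrlm_features <- function(discretized, mask = NULL, n_levels = NULL) {
  tm <- texture_matrices(discretized, mask, n_levels)
  nd <- dim(tm$glrlm)[3]
  acc <- NULL
  used <- 0
  for (d in seq_len(nd)) {
    M <- tm$glrlm[, , d]
    if (sum(M) == 0) next
    f <- rl_features_one(M, tm$n_voxels, prefix = "glrlm")
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1
  }
  if (used == 0) stop("no runs found", call. = FALSE)
  acc / used
}

# shared run-length / size-zone feature formulas: M is levels x size,
# Nv the ROI voxel count; names adapted per family
rl_features_one <- function(M, Nv, prefix) {
  Ns <- sum(M)
  p <- M / Ns
  i <- seq_len(nrow(M))
  l <- seq_len(ncol(M))
  ri <- rowSums(M)
  rl <- colSums(M)
  ii <- matrix(i, nrow(M), ncol(M))
  ll <- matrix(l, nrow(M), ncol(M), byrow = TRUE)
  mu_i <- sum(ii * p)
  mu_l <- sum(ll * p)
  nz <- p[p > 0]
  out <- c(sum(rl / l^2) / Ns,
           sum(rl * l^2) / Ns,
           sum(ri / i^2) / Ns,
           sum(ri * i^2) / Ns,
           sum(M / (ii^2 * ll^2)) / Ns,
           sum(M * ii^2 / ll^2) / Ns,
           sum(M * ll^2 / ii^2) / Ns,
           sum(M * ii^2 * ll^2) / Ns,
           sum(ri^2) / Ns,
           sum(ri^2) / Ns^2,
           sum(rl^2) / Ns,
           sum(rl^2) / Ns^2,
           Ns / Nv,
           sum((ii - mu_i)^2 * p),
           sum((ll - mu_l)^2 * p),
           -sum(nz * log2(nz)))
  names(out) <- paste0(prefix, "_", switch(prefix,
    glrlm = c("sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge",
              "lrhge", "glnu", "glnu_norm", "rlnu", "rlnu_norm",
              "run_percentage", "gl_variance", "rl_variance",
              "run_entropy"),
    glszm = c("sze", "lze", "lgze", "hgze", "szlge", "szhge", "lzlge",
              "lzhge", "glnu", "glnu_norm", "zsnu", "zsnu_norm",
              "zone_percentage", "gl_variance", "zs_variance",
              "zs_entropy")))
  out
}

#' @rdname texture_features
#' @export
glszm_features <- function(discretized, mask = NULL, n_levels = NULL) {
  tm <- texture_matrices(discretized, mask, n_levels)
  M <- glszm_from_zones(tm$glszm_zones, tm$n_levels)
  rl_features_one(M, tm$n_voxels, prefix = "glszm")
}

glszm_from_zones <- function(zones, n_levels) {
  if (nrow(zones) == 0) stop("no zones found", call. = FALSE)
  maxz <- max(zones[, 2])
  M <- matrix(0, n_levels, maxz)
  for (k in seq_len(nrow(zones)))
    M[zones[k, 1], zones[k, 2]] <- M[zones[k, 1], zones[k, 2]] + 1
  M
}

#' @rdname texture_features
#' @export
ngtdm_features <- function(discretized, mask = NULL, n_levels = NULL) {
  tm <- texture_matrices(discretized, mask, n_levels)
  ngtdm_features_from_matrix(tm$ngtdm)
}

ngtdm_features_from_matrix <- function(ng) {
  n_i <- ng[, 1]
  s_i <- ng[, 2]
  Nvc <- sum(n_i)
  if (Nvc == 0) stop("no voxels with valid neighbourhoods", call. = FALSE)
  p_i <- n_i / Nvc
  lev <- seq_along(p_i)
  act <- p_i > 0
  Ngp <- sum(act)
  ps <- sum(p_i * s_i)
  coarse <- if (ps > 0) 1 / ps else 1e6
  if (Ngp > 1) {
    ij2 <- outer(lev[act], lev[act], function(a, b) (a - b)^2)
    pp <- outer(p_i[act], p_i[act])
    contrast <- sum(pp * ij2) / (Ngp * (Ngp - 1)) * sum(s_i) / Nvc
    ipi <- lev[act] * p_i[act]
    busy_den <- sum(abs(outer(ipi, ipi, "-")))
    busy <- if (busy_den > 0) ps / busy_den else 0
    psm <- outer(p_i[act] * s_i[act], p_i[act] * s_i[act], "+")
    ppsum <- outer(p_i[act], p_i[act], "+")
    adiff <- abs(outer(lev[act], lev[act], "-"))
    complexity <- sum(adiff * psm / ppsum) / Nvc
    strength <- if (sum(s_i) > 0) sum(ppsum * ij2) / sum(s_i) else 0
  } else {
    contrast <- 0; busy <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_coarseness = coarse,
    ngtdm_contrast = contrast,
    ngtdm_busyness = busy,
    ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' @rdname texture_features
#' @export
ngldm_features <- function(discretized, mask = NULL, n_levels = NULL) {
  tm <- texture_matrices(discretized, mask, n_levels)
  ngldm_features_from_matrix(tm$ngldm, tm$n_voxels)
}

ngldm_features_from_matrix <- function(M, Nv) {
  Ns <- sum(M)
  if (Ns == 0) stop("empty dependence matrix", call. = FALSE)
  p <- M / Ns
  i <- seq_len(nrow(M))
  j <- seq_len(ncol(M))           # dependence count k shifted by +1
  ri <- rowSums(M)
  rj <- colSums(M)
  ii <- matrix(i, nrow(M), ncol(M))
  jj <- matrix(j, nrow(M), ncol(M), byrow = TRUE)
  mu_i <- sum(ii * p)
  mu_j <- sum(jj * p)
  nz <- p[p > 0]
  c(ngldm_lde = sum(rj / j^2) / Ns,
    ngldm_hde = sum(rj * j^2) / Ns,
    ngldm_lgce = sum(ri / i^2) / Ns,
    ngldm_hgce = sum(ri * i^2) / Ns,
    ngldm_ldlge = sum(M / (ii^2 * jj^2)) / Ns,
    ngldm_ldhge = sum(M * ii^2 / jj^2) / Ns,
    ngldm_hdlge = sum(M * jj^2 / ii^2) / Ns,
    ngldm_hdhge = sum(M * ii^2 * jj^2) / Ns,
    ngldm_glnu = sum(ri^2) / Ns,
    ngldm_glnu_norm = sum(ri^2) / Ns^2,
    ngldm_dcnu = sum(rj^2) / Ns,
    ngldm_dcnu_norm = sum(rj^2) / Ns^2,
    ngldm_dc_percentage = Ns / Nv,
    ngldm_gl_variance = sum((ii - mu_i)^2 * p),
    ngldm_dc_variance = sum((jj - mu_j)^2 * p),
    ngldm_dc_entropy = -sum(nz * log2(nz)),
    ngldm_dc_energy = sum(nz^2))
}
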