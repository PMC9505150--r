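#' Morphological (shape) features of an ROI mask
#'
#' Seventeen shape descriptors of the binary mask at isotropic spacing:
#' voxel-count and mesh volume, mesh surface area, surface/volume ratio,
#' compactness 1 and 2, spherical disproportion, sphericity, asphericity,
#' maximum 3D diameter, the three principal axis lengths from PCA of the
#' voxel centres, elongation, flatness, and the volume/area densities of
#' the axis-aligned bounding box. The surface mesh is an iso-surface at
#' 0.5 of the binary mask (marching tetrahedra on a lightly smoothed
#' field, see the methods vignette for the staircase-bias rationale).
#'
#' @param mask an [roi_mask()], non-empty.
#' @param spacing_mm voxel spacing (defaults to the mask's own).
#' @return Named numeric vector of length 17.
#' @export
shape_features <- function(mask, spacing_mm = mask$spacing_mm) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$values >= 0.5
  nvox <- sum(m)
  if (nvox == 0) stop("empty mask", call. = FALSE)
  vox_vol <- prod(spacing_mm)
  v_voxel <- nvox * vox_vol

  mesh <- mesh_binary_cpp(array(as.integer(m), dim(m)), spacing_mm)
  v_mesh <- mesh$volume_mm3
  a_mesh <- mesh$area_mm2
  if (v_mesh <= 0 || a_mesh <= 0) {
    # tiny masks can be smoothed away: retry without smoothing, then fall
    # back to voxel-equivalent sphere values
    mesh <- mesh_binary_cpp(array(as.integer(m), dim(m)), spacing_mm,
                            presmooth = 0L, smooth_iters = 0L)
    v_mesh <- mesh$volume_mm3
    a_mesh <- mesh$area_mm2
  }
  if (v_mesh <= 0 || a_mesh <= 0) {
    warning("degenerate mesh: falling back to voxel-based surface values")
    v_mesh <- v_voxel
    r_eq <- (3 * v_voxel / (4 * pi))^(1 / 3)
    a_mesh <- 4 * pi * r_eq^2
  }

  idx <- which(m, arr.ind = TRUE)
  centres <- sweep(idx - 1, 2, spacing_mm, "*")
  # max 3D diameter: largest pairwise distance between boundary voxel
  # centres (interior voxels cannot realize the maximum)
  bnd <- boundary_voxels(m)
  bc <- sweep(which(bnd, arr.ind = TRUE) - 1, 2, spacing_mm, "*")
  max_diam <- if (nrow(bc) == 1) 0 else sqrt(max(dist2_pairwise(bc)))

  if (nvox > 1) {
    ev <- eigen(stats::cov(centres) * (nvox - 1) / nvox,
                symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  aabb <- apply(centres, 2, range)
  side <- unname(aabb[2, ] - aabb[1, ]) + spacing_mm  # box of voxel cubes
  aabb_v <- prod(side)
  aabb_a <- 2 * (side[1] * side[2] + side[1] * side[3] + side[2] * side[3])

  r_eq <- (3 * v_mesh / (4 * pi))^(1 / 3)
  c(shape_volume_voxel = v_voxel,
    shape_volume_mesh = v_mesh,
    shape_area_mesh = a_mesh,
    shape_surface_to_volume = a_mesh / v_mesh,
    shape_compactness1 = v_mesh / (sqrt(pi) * a_mesh^1.5),
    shape_compactness2 = 36 * pi * v_mesh^2 / a_mesh^3,
    shape_spherical_disproportion = a_mesh / (4 * pi * r_eq^2),
    shape_sphericity = (36 * pi * v_mesh^2)^(1 / 3) / a_mesh,
    shape_asphericity = (a_mesh^3 / (36 * pi * v_mesh^2))^(1 / 3) - 1,
    shape_max_diameter_3d = max_diam,
    shape_major_axis_length = major,
    shape_minor_axis_length = minor,
    shape_least_axis_length = least,
    shape_elongation = elong,
    shape_flatness = flat,
    shape_aabb_volume_density = v_voxel / aabb_v,
    shape_aabb_area_density = a_mesh / aabb_a)
}

# voxels of m with at least one face-neighbour outside the mask
boundary_voxels <- function(m) {
  d <- dim(m)
  inner <- array(TRUE, d)
  shift_all <- function(arr, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1, 1))
    inner <- inner & shift_all(m, ax, by)
  m & !inner
}

# squared pairwise distances between rows (dense, small n)
dist2_pairwise <- function(x) {
  g <- rowSums(x^2)
  d2 <- outer(g, g, "+") - 2 * tcrossprod(x)
  pmax(d2, 0)
}
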