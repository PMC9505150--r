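#' Preprocessing configuration
#'
#' Bundles the tunable constants of the image-processing chain: the
#' linear-quadratic alpha/beta ratio used for BED conversion (1.5 Gy, the
#' conventional prostate value), the isotropic target spacing, the mask
#' binarization threshold applied after trilinear resampling, the number of
#' grey levels for fixed-bin-number discretization, and the PET fixed
#' threshold fraction used for uptake segmentation.
#'
#' @param alpha_beta_gy positive alpha/beta ratio in Gy (default 1.5).
#' @param target_spacing_mm length-3 target voxel spacing (default 1 mm iso).
#' @param mask_binarization_threshold fraction in (0,1) (default 0.5).
#' @param n_grey_levels integer >= 2 (default 64).
#' @param pet_threshold_fraction fraction in (0,1) of the maximum SUV
#'   (default 0.40).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(alpha_beta_gy = 1.5,
                              target_spacing_mm = c(1, 1, 1),
                              mask_binarization_threshold = 0.5,
                              n_grey_levels = 64L,
                              pet_threshold_fraction = 0.40) {
  stopifnot(alpha_beta_gy > 0, all(target_spacing_mm > 0),
            mask_binarization_threshold > 0, mask_binarization_threshold < 1,
            n_grey_levels >= 2,
            pet_threshold_fraction > 0, pet_threshold_fraction < 1)
  structure(list(alpha_beta_gy = alpha_beta_gy,
                 target_spacing_mm = as.numeric(target_spacing_mm),
                 mask_binarization_threshold = mask_binarization_threshold,
                 n_grey_levels = as.integer(n_grey_levels),
                 pet_threshold_fraction = pet_threshold_fraction),
            class = "preprocess_config")
}

#' Convert PET activity concentration to standardized uptake value
#'
#' Body-weight SUV with decay correction to injection time:
#' `SUV = c * w / (A0 * 2^(-delay / half_life))`, where `c` is the activity
#' concentration (Bq/mL), `w` the body weight (g), `A0` the injected
#' activity (Bq) and `delay` the injection-to-scan interval (s).
#'
#' @param pet an [image_volume()] in Bq/mL.
#' @param body_weight_g body weight in grams.
#' @param injected_activity_bq injected activity in Bq.
#' @param delay_s injection-to-scan interval in seconds.
#' @param half_life_s isotope half-life in seconds.
#' @return An [image_volume()] with unit `"SUV"`.
#' @export
to_suv <- function(pet, body_weight_g, injected_activity_bq, delay_s,
                   half_life_s) {
  stopifnot(inherits(pet, "image_volume"))
  if (pet$unit != "BQ_ML") stop("`pet` must be in Bq/mL", call. = FALSE)
  if (body_weight_g <= 0 || injected_activity_bq <= 0 || half_life_s <= 0)
    stop("body weight, injected activity and half-life must be positive",
         call. = FALSE)
  if (delay_s < 0) stop("`delay_s` must be non-negative", call. = FALSE)
  decayed <- injected_activity_bq * 2^(-delay_s / half_life_s)
  out <- pet
  out$values <- pet$values * body_weight_g / decayed
  out$unit <- "SUV"
  out
}

#' Convert a fractionated dose grid to biologically effective dose
#'
#' Voxel-wise linear-quadratic BED for a schedule of `n` equal fractions:
#' `BED = D * (1 + (D / n) / (alpha/beta))` with `D` the total physical dose
#' in the voxel. The prescription 35 Gy in 7 fractions at alpha/beta 1.5 Gy
#' gives 151.7 Gy.
#'
#' @param dose a [dose_grid()].
#' @param alpha_beta_gy positive alpha/beta ratio in Gy.
#' @return An [image_volume()] with unit `"BED_GY"`.
#' @export
to_bed <- function(dose, alpha_beta_gy = 1.5) {
  stopifnot(inherits(dose, "dose_grid"))
  if (alpha_beta_gy <= 0) stop("`alpha_beta_gy` must be > 0", call. = FALSE)
  d <- dose$volume$values
  out <- dose$volume
  out$values <- d * (1 + (d / dose$n_fractions) / alpha_beta_gy)
  out$unit <- "BED_GY"
  out
}

#' Crossing-number point-in-polygon test
#'
#' Casts a horizontal ray towards +x and counts boundary crossings; the
#' point is inside iff the count is odd. Edges are treated half-open in y
#' (a vertex is counted when one endpoint is strictly above the ray and the
#' other is not), which resolves vertex-touching rays deterministically.
#'
#' @param point numeric length-2 `(x, y)`.
#' @param polygon n x 2 matrix of closed-polygon vertices (n >= 3).
#' @return logical.
#' @export
point_in_polygon <- function(point, polygon) {
  if (!is.matrix(polygon) || ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("`polygon` must be an n x 2 matrix with n >= 3", call. = FALSE)
  if (polygon_area(polygon) == 0) {
    warning("degenerate (zero-area) polygon: point treated as outside")
    return(FALSE)
  }
  as.logical(points_in_polygon(matrix(point, ncol = 2), polygon))
}

# shoelace area (signed -> abs)
polygon_area <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# vectorized crossing-number test for many points against one polygon
points_in_polygon <- function(pts, polygon) {
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(polygon)
  x1 <- polygon[, 1]; y1 <- polygon[, 2]
  idx <- c(seq_len(n)[-1], 1L)
  x2 <- polygon[idx, 1]; y2 <- polygon[idx, 2]
  inside <- logical(length(px))
  for (e in seq_len(n)) {
    # half-open in y: edge active when it straddles the ray's y level
    active <- (y1[e] > py) != (y2[e] > py)
    if (any(active)) {
      xc <- x1[e] + (py[active] - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
      hit <- xc > px[active]
      inside[active][hit] <- !inside[active][hit]
    }
  }
  inside
}

#' Rasterize per-slice contours onto a reference grid
#'
#' A voxel belongs to the mask iff its centre passes the crossing-number
#' test against the polygon of the slice whose z matches the voxel plane
#' (within half a slice spacing). Slices without a polygon stay zero.
#' Multiple polygons on one slice XOR, so holes are honoured.
#'
#' @param contours a [contour_set()].
#' @param reference an [image_volume()] supplying the grid geometry.
#' @return An [roi_mask()] on the reference geometry.
#' @export
rasterize <- function(contours, reference) {
  stopifnot(inherits(contours, "contour_set"),
            inherits(reference, "image_volume"))
  dm <- dim(reference$values)
  mask <- array(0, dm)
  zc <- axis_coords(reference, 3)
  dz <- reference$spacing_mm[3]
  xs <- axis_coords(reference, 1)
  ys <- axis_coords(reference, 2)
  bad <- character()
  for (s in contours$slices) {
    k <- which(abs(zc - s$z_mm) <= dz / 2 + 1e-9)
    if (!length(k)) { bad <- c(bad, format(s$z_mm)); next }
    k <- k[which.min(abs(zc[k] - s$z_mm))]
    poly <- s$vertices
    # restrict the test to the polygon's bounding box
    ix <- which(xs >= min(poly[, 1]) - 1e-9 & xs <= max(poly[, 1]) + 1e-9)
    iy <- which(ys >= min(poly[, 2]) - 1e-9 & ys <= max(poly[, 2]) + 1e-9)
    if (!length(ix) || !length(iy)) next
    pts <- cbind(rep(xs[ix], times = length(iy)),
                 rep(ys[iy], each = length(ix)))
    inside <- points_in_polygon(pts, poly)
    sl <- mask[, , k]
    sub <- sl[ix, iy]
    sub[inside] <- 1 - sub[inside]   # XOR so nested contours cut holes
    sl[ix, iy] <- sub
    mask[, , k] <- sl
  }
  if (length(bad))
    stop("contour slice(s) at z = ", paste(bad, collapse = ", "),
         " mm fall outside the reference grid", call. = FALSE)
  roi_mask(mask, reference$spacing_mm, reference$origin_mm)
}

#' Trilinear resampling to a target spacing
#'
#' Builds an output grid covering the physical extent of the input and
#' interpolates values at the output voxel centres with trilinear weights.
#' Output values never overshoot the input range. Points outside the input
#' voxel-centre hull are clamped to the border value.
#'
#' @param volume an [image_volume()].
#' @param target_spacing_mm length-3 positive spacing of the output grid.
#' @return An [image_volume()] on the new grid, same unit.
#' @export
resample_trilinear <- function(volume, target_spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(volume, "image_volume"))
  target_spacing_mm <- as.numeric(target_spacing_mm)
  if (length(target_spacing_mm) != 3L || any(target_spacing_mm <= 0))
    stop("`target_spacing_mm` must be three positive numbers", call. = FALSE)
  dm <- dim(volume$values)
  extent <- (dm - 1) * volume$spacing_mm
  if (any(target_spacing_mm > extent + volume$spacing_mm))
    stop("target spacing exceeds the physical extent of the volume",
         call. = FALSE)
  if (isTRUE(all.equal(target_spacing_mm, volume$spacing_mm,
                       tolerance = 1e-9)))
    return(volume)
  nout <- pmax(2L, as.integer(floor(extent / target_spacing_mm + 1e-9)) + 1L)
  out_coords <- lapply(1:3, function(a)
    volume$origin_mm[a] + (seq_len(nout[a]) - 1) * target_spacing_mm[a])
  vals <- interp_trilinear(volume, out_coords[[1]], out_coords[[2]],
                           out_coords[[3]])
  image_volume(vals, target_spacing_mm, volume$origin_mm, volume$unit)
}

# trilinear interpolation of `volume` on the tensor grid (xs, ys, zs);
# fully vectorized 8-corner gather
interp_trilinear <- function(volume, xs, ys, zs) {
  dm <- dim(volume$values)
  loc <- function(coords, axis) {
    u <- (coords - volume$origin_mm[axis]) / volume$spacing_mm[axis]
    u <- pmin(pmax(u, 0), dm[axis] - 1)   # clamp to the centre hull
    i0 <- pmin(floor(u), dm[axis] - 2)
    list(i0 = as.integer(i0) + 1L, f = u - i0)  # 1-based lower corner
  }
  lx <- loc(xs, 1); ly <- loc(ys, 2); lz <- loc(zs, 3)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  ix <- rep(lx$i0, times = ny * nz)
  fx <- rep(lx$f, times = ny * nz)
  iy <- rep(rep(ly$i0, each = nx), times = nz)
  fy <- rep(rep(ly$f, each = nx), times = nz)
  iz <- rep(lz$i0, each = nx * ny)
  fz <- rep(lz$f, each = nx * ny)
  v <- volume$values
  at <- function(dx, dy, dz)
    v[cbind(ix + dx, iy + dy, iz + dz)]
  out <- at(0L, 0L, 0L) * (1 - fx) * (1 - fy) * (1 - fz) +
         at(1L, 0L, 0L) * fx       * (1 - fy) * (1 - fz) +
         at(0L, 1L, 0L) * (1 - fx) * fy       * (1 - fz) +
         at(1L, 1L, 0L) * fx       * fy       * (1 - fz) +
         at(0L, 0L, 1L) * (1 - fx) * (1 - fy) * fz +
         at(1L, 0L, 1L) * fx       * (1 - fy) * fz +
         at(0L, 1L, 1L) * (1 - fx) * fy       * fz +
         at(1L, 1L, 1L) * fx       * fy       * fz
  array(out, c(nx, ny, nz))
}

#' @rdname resample_trilinear
#' @param mask an [roi_mask()]; interpolated as a real field, then
#'   binarized at `threshold` to absorb partial-volume voxels.
#' @param threshold binarization threshold in (0,1) (default 0.5).
#' @export
resample_mask <- function(mask, target_spacing_mm = c(1, 1, 1),
                          threshold = 0.5) {
  stopifnot(inherits(mask, "roi_mask"))
  vol <- image_volume(mask$values, mask$spacing_mm, mask$origin_mm,
                      unit = "GREY_LEVEL")
  res <- resample_trilinear(vol, target_spacing_mm)
  roi_mask(array(as.numeric(res$values >= threshold), dim(res$values)),
           res$spacing_mm, res$origin_mm)
}

#' Round CT values to integer Hounsfield units
#'
#' HU are integer by definition; interpolated values are rounded to the
#' nearest integer with ties going half away from zero (-0.5 -> -1).
#'
#' @param ct an [image_volume()] in HU.
#' @return The rounded [image_volume()].
#' @export
round_ct <- function(ct) {
  stopifnot(inherits(ct, "image_volume"))
  if (ct$unit != "HU") stop("`round_ct` expects a HU volume", call. = FALSE)
  v <- ct$values
  ct$values <- sign(v) * floor(abs(v) + 0.5)
  ct
}

#' Isolate the region of interest
#'
#' Replaces every voxel outside the mask with `NA`; voxels inside are left
#' untouched. Volume and mask must share geometry exactly.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @return The masked [image_volume()].
#' @export
apply_roi <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  stop_if_geometry_differs(volume, mask)
  volume$values[mask$values < 0.5] <- NA_real_
  volume
}

#' Fixed-bin-number discretization
#'
#' Maps the non-missing intensities of a masked volume onto `n_levels`
#' equal-width grey levels between the ROI minimum and maximum:
#' `g = min(floor(n * (x - min) / (max - min)) + 1, n)`. A constant ROI maps
#' everything to level 1. The result is invariant to affine rescaling of
#' the ROI intensities.
#'
#' @param masked an [image_volume()] with `NA` outside the ROI.
#' @param n_levels number of grey levels (default 64).
#' @return An [image_volume()] of unit `"GREY_LEVEL"` carrying attribute
#'   `n_levels`.
#' @export
discretize_fbn <- function(masked, n_levels = 64L) {
  stopifnot(inherits(masked, "image_volume"), n_levels >= 2)
  v <- masked$values
  inside <- !is.na(v)
  if (!any(inside)) stop("empty ROI: nothing to discretize", call. = FALSE)
  lo <- min(v[inside]); hi <- max(v[inside])
  g <- v
  if (hi == lo) {
    g[inside] <- 1
  } else {
    g[inside] <- pmin(floor(n_levels * (v[inside] - lo) / (hi - lo)) + 1,
                      n_levels)
  }
  out <- masked
  out$values <- g
  out$unit <- "GREY_LEVEL"
  attr(out, "n_levels") <- as.integer(n_levels)
  out
}

#' Fixed-threshold PET uptake segmentation
#'
#' Keeps the voxels of a search region whose SUV reaches `fraction` of the
#' regional maximum, restricted to the 26-connected component containing
#' that maximum (so a second hot spot above threshold is discarded).
#'
#' @param pet_suv an [image_volume()] in SUV.
#' @param search_mask an [roi_mask()] delimiting the search region.
#' @param fraction threshold fraction of the maximum (default 0.40).
#' @return An [roi_mask()] of the segmented uptake volume.
#' @export
segment_pet_fixed_threshold <- function(pet_suv, search_mask,
                                        fraction = 0.40) {
  stopifnot(inherits(pet_suv, "image_volume"), inherits(search_mask, "roi_mask"))
  stop_if_geometry_differs(pet_suv, search_mask)
  region <- search_mask$values >= 0.5
  if (!any(region)) stop("empty search region", call. = FALSE)
  vals <- pet_suv$values
  vmax <- max(vals[region])
  vmin <- min(vals[region])
  if (vmax == vmin) {
    warning("search region has constant intensity: returning whole region")
    return(roi_mask(array(as.numeric(region), dim(region)),
                    search_mask$spacing_mm, search_mask$origin_mm))
  }
  above <- region & vals >= fraction * vmax
  lab <- array(label_components_26(array(as.integer(above), dim(above))),
               dim(above))
  peak <- which(region & vals == vmax)[1]
  keep <- lab == lab[peak]
  roi_mask(array(as.numeric(keep), dim(keep)),
           search_mask$spacing_mm, search_mask$origin_mm)
}

#' Run the full preprocessing chain on one patient
#'
#' Applies, in order: SUV and BED conversion on the native grids,
#' rasterization of the GTV contours on the CT grid, resampling of PET and
#' dose onto the CT frame when the grids differ, trilinear resampling of all
#' volumes and the mask to the target spacing, mask binarization, HU
#' rounding, ROI isolation, and fixed-bin-number discretization of each
#' modality.
#'
#' @param record a `patient_record` (see [generate_patient()] /
#'   [read_patient()]).
#' @param config a [preprocess_config()].
#' @return A list with masked continuous volumes (`ct`, `suv`, `bed`),
#'   their discretized counterparts (`ct_d`, `suv_d`, `bed_d`), the binary
#'   `mask`, and the voxel spacing used.
#' @export
preprocess_patient <- function(record, config = preprocess_config()) {
  stopifnot(inherits(record, "patient_record"),
            inherits(config, "preprocess_config"))
  suv <- to_suv(record$pet, record$radiopharm$body_weight_g,
                record$radiopharm$injected_activity_bq,
                record$radiopharm$delay_s, record$radiopharm$half_life_s)
  bed <- to_bed(record$dose, config$alpha_beta_gy)
  mask0 <- rasterize(record$gtv, record$ct)
  # bring PET/dose onto the CT frame first if planned on a different grid
  if (!same_geometry(suv, record$ct))
    suv <- resample_onto(suv, record$ct)
  if (!same_geometry(bed, record$ct))
    bed <- resample_onto(bed, record$ct)
  ts <- config$target_spacing_mm
  ct1 <- resample_trilinear(record$ct, ts)
  suv1 <- resample_trilinear(suv, ts)
  bed1 <- resample_trilinear(bed, ts)
  mask1 <- resample_mask(mask0, ts, config$mask_binarization_threshold)
  ct1 <- round_ct(ct1)
  ct_m <- apply_roi(ct1, mask1)
  suv_m <- apply_roi(suv1, mask1)
  bed_m <- apply_roi(bed1, mask1)
  list(ct = ct_m, suv = suv_m, bed = bed_m,
       ct_d = discretize_fbn(ct_m, config$n_grey_levels),
       suv_d = discretize_fbn(suv_m, config$n_grey_levels),
       bed_d = discretize_fbn(bed_m, config$n_grey_levels),
       mask = mask1, spacing_mm = ts)
}

# interpolate `volume` onto the grid of `reference` (same unit kept)
resample_onto <- function(volume, reference) {
  vals <- interp_trilinear(volume, axis_coords(reference, 1),
                           axis_coords(reference, 2), axis_coords(reference, 3))
  image_volume(vals, reference$spacing_mm, reference$origin_mm, volume$unit)
}
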