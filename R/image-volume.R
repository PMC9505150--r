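#' Volumetric image with physical geometry
#'
#' A 3D scalar grid plus the metadata needed to place every voxel in patient
#' coordinates: voxel spacing, origin, and an intensity unit tag. Indices are
#' 0-based in the coordinate convention; the centre of voxel (0,0,0) sits at
#' `origin_mm`. Only axial identity orientation is supported; oblique
#' direction cosines are rejected.
#'
#' @param values numeric 3D array.
#' @param spacing_mm numeric length-3, strictly positive voxel spacing (mm).
#' @param origin_mm numeric length-3 position of the first voxel centre (mm).
#' @param unit one of `"HU"`, `"BQ_ML"`, `"SUV"`, `"GY"`, `"BED_GY"`,
#'   `"GREY_LEVEL"`.
#' @param direction 3x3 direction-cosine matrix; must be the identity.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                         unit = c("HU", "BQ_ML", "SUV", "GY", "BED_GY",
                                  "GREY_LEVEL"),
                         direction = diag(3)) {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive numbers", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be three finite numbers", call. = FALSE)
  if (!isTRUE(all.equal(unname(direction), diag(3), tolerance = 1e-6)))
    stop("oblique image orientations are not supported: direction cosines ",
         "must be the axial identity", call. = FALSE)
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm,
         unit = unit),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d voxels [%s]\n", d[1], d[2], d[3],
              x$unit))
  cat(sprintf("  spacing: %s mm, origin: %s mm\n",
              paste(signif(x$spacing_mm, 4), collapse = " x "),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  range: [%.4g, %.4g] (%d finite voxels)\n",
                min(v), max(v), length(v)))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' Geometry-carrying companion of [image_volume()] whose voxels are 0/1
#' (or fractional in `[0,1]` between resampling and binarization).
#'
#' @param values numeric/logical 3D array with values in `[0,1]`.
#' @inheritParams image_volume
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (is.logical(values)) values <- array(as.numeric(values), dim(values))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("mask values must lie in [0, 1]", call. = FALSE)
  vol <- image_volume(values, spacing_mm, origin_mm, unit = "GREY_LEVEL")
  structure(list(values = vol$values, spacing_mm = vol$spacing_mm,
                 origin_mm = vol$origin_mm), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<roi_mask> %d x %d x %d voxels, %d inside\n",
              d[1], d[2], d[3], sum(x$values >= 0.5)))
  invisible(x)
}

#' Planar contour stack for one region of interest
#'
#' Per-slice closed polygons in patient coordinates, the native form of a
#' radiotherapy structure set ROI. Each slice is a list with `z_mm` and an
#' n x 2 `vertices` matrix (x, y in mm); the polygon is implicitly closed.
#'
#' @param roi_name name of the structure (e.g. `"GTV"`).
#' @param slices list of `list(z_mm =, vertices =)` entries.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(roi_name, slices) {
  for (s in slices) {
    if (is.null(s$z_mm) || is.null(s$vertices) || !is.matrix(s$vertices) ||
        ncol(s$vertices) != 2L || nrow(s$vertices) < 3L)
      stop("each contour slice needs `z_mm` and an n x 2 vertex matrix ",
           "with n >= 3", call. = FALSE)
  }
  structure(list(roi_name = as.character(roi_name), slices = slices),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> '%s': %d slices, %s vertices/slice\n",
              x$roi_name, length(x$slices),
              if (length(x$slices))
                paste(range(vapply(x$slices, function(s) nrow(s$vertices),
                                   1L)), collapse = "-")
              else "0"))
  invisible(x)
}

#' Dose grid with fractionation
#'
#' @param volume an [image_volume()] in Gy (total physical dose).
#' @param n_fractions number of fractions the dose was delivered in.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(volume, n_fractions) {
  stopifnot(inherits(volume, "image_volume"))
  if (volume$unit != "GY") stop("dose volume must have unit 'GY'", call. = FALSE)
  if (any(volume$values < 0, na.rm = TRUE))
    stop("dose values must be non-negative", call. = FALSE)
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("`n_fractions` must be a count >= 1", call. = FALSE)
  structure(list(volume = volume, n_fractions = n_fractions),
            class = "dose_grid")
}

# physical coordinate of voxel centres along one axis (0-based index)
axis_coords <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin_mm[axis] + (seq_len(n) - 1) * vol$spacing_mm[axis]
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing_mm - b$spacing_mm)) < tol &&
    max(abs(a$origin_mm - b$origin_mm)) < tol
}

stop_if_geometry_differs <- function(a, b) {
  if (!same_geometry(a, b))
    stop("volume and mask geometries differ (dims/spacing/origin)",
         call. = FALSE)
  invisible(TRUE)
}
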