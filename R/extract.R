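#' The fixed 380-feature catalogue
#'
#' Seventeen shape features computed once from the GTV mask, plus 121
#' features per modality (18 intensity statistics, 23 histogram features,
#' integrated intensity, 25 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM and 17
#' NGLDM texture features) for CT, PET-SUV and BED, 380 in total. The
#' catalogue is data: a data frame with one row per feature in canonical
#' order.
#'
#' @return A data frame with columns `name`, `family`, `modality`.
#' @export
feature_catalogue <- function() {
  shp <- c("volume_voxel", "volume_mesh", "area_mesh", "surface_to_volume",
           "compactness1", "compactness2", "spherical_disproportion",
           "sphericity", "asphericity", "max_diameter_3d",
           "major_axis_length", "minor_axis_length", "least_axis_length",
           "elongation", "flatness", "aabb_volume_density",
           "aabb_area_density")
  stat <- c("mean", "variance", "skewness", "kurtosis", "median", "min",
            "p10", "p90", "max", "iqr", "range", "mad", "robust_mad",
            "median_ad", "cov", "qcod", "energy", "rms")
  hst <- c("mean", "variance", "skewness", "kurtosis", "median", "min",
           "p10", "p90", "max", "mode", "iqr", "range", "mad",
           "robust_mad", "median_ad", "cov", "qcod", "entropy",
           "uniformity", "max_gradient", "max_gradient_level",
           "min_gradient", "min_gradient_level")
  glcm <- c("joint_max", "joint_average", "joint_variance", "joint_entropy",
            "diff_average", "diff_variance", "diff_entropy", "sum_average",
            "sum_variance", "sum_entropy", "energy", "contrast",
            "dissimilarity", "inverse_difference",
            "inverse_difference_norm", "inverse_difference_moment",
            "inverse_difference_moment_norm", "inverse_variance",
            "correlation", "autocorrelation", "cluster_tendency",
            "cluster_shade", "cluster_prominence", "info_corr1",
            "info_corr2")
  glrlm <- c("sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge",
             "lrhge", "glnu", "glnu_norm", "rlnu", "rlnu_norm",
             "run_percentage", "gl_variance", "rl_variance", "run_entropy")
  glszm <- c("sze", "lze", "lgze", "hgze", "szlge", "szhge", "lzlge",
             "lzhge", "glnu", "glnu_norm", "zsnu", "zsnu_norm",
             "zone_percentage", "gl_variance", "zs_variance", "zs_entropy")
  ngtdm <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  ngldm <- c("lde", "hde", "lgce", "hgce", "ldlge", "ldhge", "hdlge",
             "hdhge", "glnu", "glnu_norm", "dcnu", "dcnu_norm",
             "dc_percentage", "gl_variance", "dc_variance", "dc_entropy",
             "dc_energy")
  per_mod <- rbind(
    data.frame(family = "STATS", feat = paste0("stat_", stat)),
    data.frame(family = "HISTOGRAM", feat = paste0("hist_", hst)),
    data.frame(family = "INTEGRATED_INTENSITY", feat = "integrated_intensity"),
    data.frame(family = "GLCM", feat = paste0("glcm_", glcm)),
    data.frame(family = "GLRLM", feat = paste0("glrlm_", glrlm)),
    data.frame(family = "GLSZM", feat = paste0("glszm_", glszm)),
    data.frame(family = "NGTDM", feat = paste0("ngtdm_", ngtdm)),
    data.frame(family = "NGLDM", feat = paste0("ngldm_", ngldm)))
  out <- rbind(
    data.frame(name = paste0("shape_", shp), family = "SHAPE",
               modality = "MASK"),
    do.call(rbind, lapply(c("CT", "PET", "BED"), function(m)
      data.frame(name = paste0(m, "_", per_mod$feat),
                 family = per_mod$family, modality = m))))
  rownames(out) <- NULL
  stopifnot(nrow(out) == 380L, !anyDuplicated(out$name))
  out
}

# all 121 per-modality features from the masked continuous volume and its
# discretized companion; texture matrices built once and shared
modality_features <- function(masked, discretized, mask) {
  tm <- texture_matrices(discretized)
  c(intensity_statistics(masked),
    histogram_features(discretized),
    integrated_intensity(masked, mask),
    glcm_features_from_matrices(tm$glcm),
    glrlm_features_agg(tm),
    rl_features_one(glszm_from_zones(tm$glszm_zones, tm$n_levels),
                    tm$n_voxels, prefix = "glszm"),
    ngtdm_features_from_matrix(tm$ngtdm),
    ngldm_features_from_matrix(tm$ngldm, tm$n_voxels))
}

glrlm_features_agg <- function(tm) {
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

#' Extract the full 380-feature vector of one patient
#'
#' Computes the 17 shape features from the GTV mask once and the 121
#' per-modality features for CT, PET-SUV and BED on the preprocessed
#' bundle, in the canonical [feature_catalogue()] order with modality
#' prefixes `CT_` / `PET_` / `BED_`. The ROI is cropped to its bounding
#' box before texture computation (a translation, to which all features
#' are invariant).
#'
#' @param pre output of [preprocess_patient()], or a compatible list with
#'   elements `ct`, `suv`, `bed`, `ct_d`, `suv_d`, `bed_d`, `mask`.
#' @return Named numeric vector of length 380.
#' @export
extract_all <- function(pre) {
  need <- c("ct", "suv", "bed", "ct_d", "suv_d", "bed_d", "mask")
  miss <- setdiff(need, names(pre))
  if (length(miss))
    stop("preprocessed bundle is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (nm in c("ct", "suv", "bed"))
    stop_if_geometry_differs(pre[[nm]], pre$mask)
  bb <- mask_bbox(pre$mask$values >= 0.5)
  crop <- function(vol) {
    vol$values <- vol$values[bb$x, bb$y, bb$z, drop = FALSE]
    vol
  }
  mask_c <- pre$mask
  mask_c$values <- mask_c$values[bb$x, bb$y, bb$z, drop = FALSE]
  out <- c(
    shape_features(pre$mask),
    prefix_names("CT", modality_features(crop(pre$ct), crop(pre$ct_d), mask_c)),
    prefix_names("PET", modality_features(crop(pre$suv), crop(pre$suv_d), mask_c)),
    prefix_names("BED", modality_features(crop(pre$bed), crop(pre$bed_d), mask_c)))
  cat380 <- feature_catalogue()$name
  stopifnot(identical(names(out), cat380))
  if (any(!is.finite(out)))
    stop("non-finite feature values: ",
         paste(names(out)[!is.finite(out)], collapse = ", "), call. = FALSE)
  out
}

prefix_names <- function(prefix, x) {
  names(x) <- paste0(prefix, "_", names(x))
  x
}

mask_bbox <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask", call. = FALSE)
  list(x = min(idx[, 1]):max(idx[, 1]),
       y = min(idx[, 2]):max(idx[, 2]),
       z = min(idx[, 3]):max(idx[, 3]))
}

#' Extract features for a whole cohort
#'
#' Runs [preprocess_patient()] and [extract_all()] on each record and
#' binds the results into a feature table.
#'
#' @param cohort list of `patient_record`s.
#' @param config a [preprocess_config()].
#' @param verbose print progress every 25 patients.
#' @return A data frame: `patient_id`, `event`, `time_months`, then the
#'   380 feature columns.
#' @export
extract_cohort <- function(cohort, config = preprocess_config(),
                           verbose = FALSE) {
  rows <- vector("list", length(cohort))
  for (k in seq_along(cohort)) {
    rec <- cohort[[k]]
    fv <- extract_all(preprocess_patient(rec, config))
    rows[[k]] <- data.frame(patient_id = rec$patient_id,
                            event = rec$event,
                            time_months = rec$time_months,
                            as.list(fv), check.names = FALSE)
    if (verbose && k %% 25 == 0)
      message(sprintf("extracted %d / %d patients", k, length(cohort)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
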