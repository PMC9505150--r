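#' Write a cohort to the portable container format
#'
#' One directory per patient holding raw little-endian float32 volumes
#' (`ct.f32`, `pet.f32`, `dose.f32`), a JSON sidecar `meta.json` (shape,
#' spacing, origin, units, fraction count, radiopharmaceutical data,
#' outcome) and the GTV polygons in `gtv.json`; plus a cohort
#' `manifest.csv` (patient_id, event, time_months). An empty cohort
#' writes no files and returns an empty manifest.
#'
#' @param cohort list of `patient_record`s.
#' @param directory destination directory (created if needed).
#' @param format only `"container"` is supported.
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, directory, format = "container") {
  if (!identical(format, "container"))
    stop("unsupported format: ", format, call. = FALSE)
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  manifest <- data.frame(patient_id = character(), event = logical(),
                         time_months = numeric())
  if (!length(cohort)) return(invisible(manifest))
  for (rec in cohort) write_patient(rec, file.path(directory, rec$patient_id))
  manifest <- data.frame(
    patient_id = vapply(cohort, function(r) r$patient_id, ""),
    event = vapply(cohort, function(r) r$event, TRUE),
    time_months = vapply(cohort, function(r) r$time_months, 1))
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

write_patient <- function(record, directory) {
  stopifnot(inherits(record, "patient_record"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  wv <- function(vol, file) {
    con <- file(file.path(directory, file), "wb")
    on.exit(close(con))
    writeBin(as.numeric(vol$values), con, size = 4L, endian = "little")
  }
  wv(record$ct, "ct.f32")
  wv(record$pet, "pet.f32")
  wv(record$dose$volume, "dose.f32")
  geom <- function(vol)
    list(shape = dim(vol$values), spacing_mm = vol$spacing_mm,
         origin_mm = vol$origin_mm, unit = vol$unit)
  meta <- list(patient_id = record$patient_id,
               ct = geom(record$ct), pet = geom(record$pet),
               dose = c(geom(record$dose$volume),
                        list(n_fractions = record$dose$n_fractions)),
               radiopharm = record$radiopharm,
               outcome = list(event = record$event,
                              time_months = record$time_months))
  jsonlite::write_json(meta, file.path(directory, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  gtv <- list(roi_name = record$gtv$roi_name,
              slices = lapply(record$gtv$slices, function(s)
                list(z_mm = s$z_mm, x_mm = s$vertices[, 1],
                     y_mm = s$vertices[, 2])))
  jsonlite::write_json(gtv, file.path(directory, "gtv.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Read one patient from a portable container directory
#'
#' Restores the volumes in patient coordinates. Dose values are multiplied
#' by the sidecar's `dose_grid_scaling` when present (the stored-value ×
#' scaling contract of radiotherapy dose exports); CT and PET are stored
#' already rescaled. The structure set must contain the requested ROI.
#'
#' @param directory a patient directory written by [write_cohort()].
#' @param roi_name name of the ROI to extract (default `"GTV"`).
#' @return A `patient_record`.
#' @export
read_patient <- function(directory, roi_name = "GTV") {
  if (!dir.exists(directory))
    stop("no such patient directory: ", directory, call. = FALSE)
  mf <- file.path(directory, "meta.json")
  if (!file.exists(mf))
    stop("metadata sidecar (meta.json) absent in ", directory, call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  rv <- function(file, g, unit) {
    path <- file.path(directory, file)
    if (!file.exists(path))
      stop("image series absent: ", file, call. = FALSE)
    n <- prod(g$shape)
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
    if (length(vals) != n)
      stop("truncated volume file: ", file, call. = FALSE)
    image_volume(array(vals, g$shape), g$spacing_mm, g$origin_mm, unit)
  }
  ct <- rv("ct.f32", meta$ct, "HU")
  pet <- rv("pet.f32", meta$pet, "BQ_ML")
  dvol <- rv("dose.f32", meta$dose, "GY")
  if (!is.null(meta$dose$dose_grid_scaling))
    dvol$values <- dvol$values * meta$dose$dose_grid_scaling
  dose <- dose_grid(dvol, meta$dose$n_fractions)
  gf <- file.path(directory, "gtv.json")
  if (!file.exists(gf))
    stop("structure set absent (gtv.json) in ", directory, call. = FALSE)
  g <- jsonlite::read_json(gf, simplifyVector = TRUE)
  if (!identical(g$roi_name, roi_name))
    stop("ROI '", roi_name, "' absent from structure set (found '",
         g$roi_name, "')", call. = FALSE)
  slices <- lapply(seq_len(nrow(g$slices)), function(k)
    list(z_mm = g$slices$z_mm[k],
         vertices = cbind(unlist(g$slices$x_mm[k]),
                          unlist(g$slices$y_mm[k]))))
  structure(list(patient_id = meta$patient_id, ct = ct, pet = pet,
                 radiopharm = meta$radiopharm, dose = dose,
                 gtv = contour_set(g$roi_name, slices),
                 event = isTRUE(meta$outcome$event),
                 time_months = meta$outcome$time_months),
            class = "patient_record")
}

#' Read a whole cohort directory
#'
#' @param directory directory written by [write_cohort()].
#' @param roi_name ROI to extract for each patient.
#' @return List of `patient_record`s in manifest order.
#' @export
read_cohort <- function(directory, roi_name = "GTV") {
  mf <- file.path(directory, "manifest.csv")
  if (!file.exists(mf))
    stop("cohort manifest absent in ", directory, call. = FALSE)
  manifest <- utils::read.csv(mf)
  lapply(manifest$patient_id, function(id)
    read_patient(file.path(directory, id), roi_name))
}
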