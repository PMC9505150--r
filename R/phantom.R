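#' Parameters of the synthetic phantom cohort
#'
#' Defines the study conditions the generator emulates: a small salvage
#' re-irradiation cohort (43 patients, 30.2% three-year local-failure
#' prevalence), a GTV of a few cm^3 drawn as per-slice polygons around a
#' jittered ellipsoid, a choline-PET-like uptake focus, and an SBRT-like
#' dose of 35 Gy in 7 fractions with a high plateau and steep penumbra.
#' The outcome is planted on the standardized within-GTV BED variance via
#' a logistic model with coefficient `effect_size`.
#'
#' @param n_patients cohort size (default 43).
#' @param prevalence expected positive fraction in (0,1) (default 0.302).
#' @param grid_shape voxels per axis of the native grids.
#' @param spacing_mm native voxel spacing in mm (CT-like in-plane, coarser
#'   slices).
#' @param gtv_radius_mm `c(mean, jitter)`: mean GTV radius and the SD of
#'   the per-axis semi-axis jitter, both mm.
#' @param dose_prescription_gy total prescribed dose (default 35).
#' @param n_fractions fraction count (default 7).
#' @param dose_heterogeneity relative scale of the within-GTV dose
#'   texture (SD of the multiplicative field; default 0.05).
#' @param effect_size log-odds per SD of within-GTV BED variance
#'   (default 2).
#' @param penumbra_mm sigmoid fall-off scale of the dose edge (default 5).
#' @param margin_mm plateau expansion beyond the GTV surface (default 3).
#' @param seed integer master seed.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(n_patients = 43L, prevalence = 0.302,
                           grid_shape = c(48L, 48L, 28L),
                           spacing_mm = c(1.25, 1.25, 2.5),
                           gtv_radius_mm = c(8, 0.5),
                           dose_prescription_gy = 35, n_fractions = 7L,
                           dose_heterogeneity = 0.05, effect_size = 2,
                           penumbra_mm = 5, margin_mm = 3, seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, all(spacing_mm > 0),
            n_fractions >= 1, dose_heterogeneity >= 0,
            length(gtv_radius_mm) == 2, gtv_radius_mm[1] > 0,
            gtv_radius_mm[2] >= 0, penumbra_mm > 0)
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence,
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 gtv_radius_mm = as.numeric(gtv_radius_mm),
                 dose_prescription_gy = dose_prescription_gy,
                 n_fractions = as.integer(n_fractions),
                 dose_heterogeneity = dose_heterogeneity,
                 effect_size = effect_size,
                 penumbra_mm = penumbra_mm, margin_mm = margin_mm,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# smooth zero-mean unit-SD random field: white noise on a coarse grid,
# trilinearly upsampled onto the target grid
correlated_noise <- function(dims, spacing, coarse_mm = 6) {
  nc <- pmax(2L, ceiling((dims - 1) * spacing / coarse_mm) + 1L)
  coarse <- image_volume(array(rnorm(prod(nc)), nc), (dims - 1) * spacing /
                           pmax(nc - 1L, 1L), c(0, 0, 0), unit = "GREY_LEVEL")
  xs <- (seq_len(dims[1]) - 1) * spacing[1]
  ys <- (seq_len(dims[2]) - 1) * spacing[2]
  zs <- (seq_len(dims[3]) - 1) * spacing[3]
  f <- interp_trilinear(coarse, xs, ys, zs)
  s <- stats::sd(f)
  if (s > 0) (f - mean(f)) / s else f * 0
}

#' Generate one synthetic patient
#'
#' Builds co-registered CT (soft-tissue background with correlated noise),
#' PET (ellipsoidal uptake focus, peak at least 4x background), and dose
#' (prescription plateau over the expanded GTV, cosine-sigmoid penumbra,
#' within-GTV multiplicative texture) volumes plus GTV contours as
#' per-slice 24-vertex polygons around the jittered ellipsoid. Fully
#' deterministic given `seed`; the outcome fields carry placeholders that
#' [generate_cohort()] overwrites.
#'
#' @param params a [phantom_params()].
#' @param patient_id identifier string.
#' @param seed integer seed for this patient's randomness.
#' @return A `patient_record`: list with `patient_id`, `ct`, `pet`,
#'   `radiopharm`, `dose`, `gtv`, `event`, `time_months`.
#' @export
generate_patient <- function(params, patient_id = "P001",
                             seed = params$seed) {
  stopifnot(inherits(params, "phantom_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)

  dm <- params$grid_shape
  sp <- params$spacing_mm
  extent <- (dm - 1) * sp
  centre <- extent / 2 + runif(3, -1, 1)       # jittered placement
  r0 <- params$gtv_radius_mm[1]
  jit <- params$gtv_radius_mm[2]
  axes <- r0 + pmin(pmax(rnorm(3, 0, jit), -2 * jit), 2 * jit)
  # angular wobble shared by all slices so the shape is a smooth blob
  wob_a <- rnorm(3, 0, 0.02)
  wob_p <- runif(3, 0, 2 * pi)
  wobble <- function(theta)
    1 + wob_a[1] * sin(2 * theta + wob_p[1]) +
        wob_a[2] * sin(3 * theta + wob_p[2]) +
        wob_a[3] * sin(5 * theta + wob_p[3])

  reach <- max(axes) * 1.1 + params$margin_mm
  if (any(centre - reach < 0) || any(centre + reach > extent))
    stop("GTV (with margin) does not fit inside the image grid; enlarge ",
         "`grid_shape` or shrink `gtv_radius_mm`", call. = FALSE)

  xs <- (seq_len(dm[1]) - 1) * sp[1]
  ys <- (seq_len(dm[2]) - 1) * sp[2]
  zs <- (seq_len(dm[3]) - 1) * sp[3]
  gx <- array(rep(xs, times = dm[2] * dm[3]), dm)
  gy <- array(rep(rep(ys, each = dm[1]), times = dm[3]), dm)
  gz <- array(rep(zs, each = dm[1] * dm[2]), dm)
  # ellipsoidal radius fraction (1 on the nominal GTV surface)
  rho <- sqrt(((gx - centre[1]) / axes[1])^2 +
              ((gy - centre[2]) / axes[2])^2 +
              ((gz - centre[3]) / axes[3])^2)
  rbar <- prod(axes)^(1 / 3)

  ct_vals <- 40 + 10 * correlated_noise(dm, sp)
  ct <- image_volume(ct_vals, sp, c(0, 0, 0), unit = "HU")

  pet_bg <- 1000
  pet_peak <- runif(1, 6000, 9000)
  pet_vals <- pet_bg * (1 + 0.10 * correlated_noise(dm, sp)) +
    pet_peak * exp(-rho^2 / (2 * 0.55^2))
  pet_vals[pet_vals < 0] <- 0
  pet <- image_volume(pet_vals, sp, c(0, 0, 0), unit = "BQ_ML")
  radiopharm <- list(body_weight_g = runif(1, 65, 95) * 1000,
                     injected_activity_bq = runif(1, 300, 450) * 1e6,
                     delay_s = runif(1, 3000, 4200),
                     half_life_s = 1223.4)     # 11C

  # distance beyond the GTV surface, approximated radially
  dist_mm <- (rho - 1) * rbar
  fall <- numeric(length(dist_mm))
  fall[dist_mm <= params$margin_mm] <- 1
  tz <- dist_mm > params$margin_mm &
        dist_mm < params$margin_mm + 2 * params$penumbra_mm
  fall[tz] <- 0.5 * (1 + cos(pi * (dist_mm[tz] - params$margin_mm) /
                               (2 * params$penumbra_mm)))
  het_scale <- params$dose_heterogeneity *
    exp(rnorm(1, 0, 0.5))                     # patient-level texture spread
  gfield <- if (params$dose_heterogeneity > 0)
    correlated_noise(dm, sp, coarse_mm = 5) else array(0, dm)
  dose_vals <- params$dose_prescription_gy * array(fall, dm) *
    (1 + het_scale * gfield)
  dose_vals[dose_vals < 0] <- 0
  dose <- dose_grid(image_volume(dose_vals, sp, c(0, 0, 0), unit = "GY"),
                    params$n_fractions)

  # per-slice polygons of the wobbled ellipsoid
  slices <- list()
  for (k in seq_len(dm[3])) {
    dzn <- (zs[k] - centre[3]) / axes[3]
    if (abs(dzn) >= 0.999) next
    sc <- sqrt(1 - dzn^2)
    if (sc * min(axes[1:2]) < 0.3) next
    theta <- seq(0, 2 * pi, length.out = 25L)[-25L]
    w <- wobble(theta)
    vx <- centre[1] + axes[1] * sc * w * cos(theta)
    vy <- centre[2] + axes[2] * sc * w * sin(theta)
    slices[[length(slices) + 1L]] <- list(z_mm = zs[k],
                                          vertices = cbind(vx, vy))
  }
  if (length(slices) < 2)
    stop("GTV spans fewer than two slices; decrease slice spacing",
         call. = FALSE)
  gtv <- contour_set("GTV", slices)

  # generator bookkeeping: the planted outcome driver
  bed_gtv <- to_bed(dose, 1.5)$values[rho < 1]
  rec <- structure(list(patient_id = patient_id, ct = ct, pet = pet,
                        radiopharm = radiopharm, dose = dose, gtv = gtv,
                        event = FALSE, time_months = 60),
                   class = "patient_record")
  attr(rec, "bed_var_gtv") <- stats::var(bed_gtv)
  rec
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s: %s, follow-up %.1f months\n",
              x$patient_id,
              if (x$event) "local failure" else "failure-free",
              x$time_months))
  cat(sprintf("  CT %s | PET %s | dose %s Gy x %d fx | GTV %d slices\n",
              paste(dim(x$ct$values), collapse = "x"),
              paste(dim(x$pet$values), collapse = "x"),
              format(max(x$dose$volume$values), digits = 3),
              x$dose$n_fractions, length(x$gtv$slices)))
  invisible(x)
}

#' Generate a synthetic cohort with a planted outcome signal
#'
#' Generates `n_patients` phantoms, standardizes their within-GTV BED
#' variance across the cohort, and draws each outcome from
#' `logit(p) = a + effect_size * z` where the intercept `a` is calibrated
#' by bisection so the expected prevalence matches `params$prevalence`.
#' Event times are uniform on (6, 35) months; failure-free follow-up is
#' uniform on (12, 102) months, so every event falls inside the 36-month
#' horizon.
#'
#' @param params a [phantom_params()].
#' @return List of `patient_record`s with `event`/`time_months` filled in.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  if (params$n_patients < 10)
    stop("cohort generation needs n_patients >= 10", call. = FALSE)
  cohort <- vector("list", params$n_patients)
  zraw <- numeric(params$n_patients)
  for (i in seq_len(params$n_patients)) {
    seed_i <- (params$seed %% 1000003L) * 2099L + i
    cohort[[i]] <- generate_patient(params, sprintf("P%03d", i), seed_i)
    zraw[i] <- attr(cohort[[i]], "bed_var_gtv")
  }
  z <- if (stats::sd(zraw) > 0) (zraw - mean(zraw)) / stats::sd(zraw)
       else zraw * 0
  a <- calibrate_intercept(z, params$effect_size, params$prevalence)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((params$seed %% 1000003L) * 2099L + 999983L)
  p <- stats::plogis(a + params$effect_size * z)
  ev <- rbinom(params$n_patients, 1, p) == 1
  tm <- ifelse(ev, runif(params$n_patients, 6, 35),
               runif(params$n_patients, 12, 102))
  for (i in seq_len(params$n_patients)) {
    cohort[[i]]$event <- ev[i]
    cohort[[i]]$time_months <- tm[i]
  }
  cohort
}

# bisection on the logistic intercept so mean p equals the target
calibrate_intercept <- function(z, beta, target) {
  f <- function(a) mean(stats::plogis(a + beta * z)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("prevalence calibration failed to bracket the target", call. = FALSE)
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# save/restore the global RNG state so generators are pure functions of
# their seed without disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
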