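binom_ci95 <- function(k, n) {
  p <- k / n
  p + c(-1.96, 1.96) * sqrt(p * (1 - p) / n)
}

test_that("a phantom patient is deterministic and physically coherent", {
  params <- tiny_phantom_params(seed = 3)
  r1 <- generate_patient(params, "P1", 42)
  r2 <- generate_patient(params, "P1", 42)
  expect_identical(r1, r2)                     # bit-identical given seed
  r3 <- generate_patient(params, "P1", 43)
  expect_false(identical(r1$ct$values, r3$ct$values))

  # CT is soft-tissue-like, PET peak at least 4x background
  expect_equal(mean(r1$ct$values), 40, tolerance = 5)
  pet <- r1$pet$values
  expect_gte(max(pet), 4 * median(pet))

  # every contour slice has >= 8 vertices
  expect_true(all(vapply(r1$gtv$slices,
                         function(s) nrow(s$vertices), 1L) >= 8L))

  # a GTV that cannot fit inside the grid is rejected
  big <- tiny_phantom_params(gtv_radius_mm = c(40, 0), seed = 3)
  expect_error(generate_patient(big, "P1", 1), "fit inside")
})

test_that("zero heterogeneity puts exactly the prescription inside the GTV", {
  params <- tiny_phantom_params(dose_heterogeneity = 0, seed = 8)
  rec <- generate_patient(params, "P1", 8)
  mask <- rasterize(rec$gtv, rec$ct)
  inside <- mask$values == 1
  dose_in <- rec$dose$volume$values[inside]
  expect_true(all(abs(dose_in - params$dose_prescription_gy) < 1e-9))
  # fall-off: far-away voxels receive (almost) nothing
  corner <- rec$dose$volume$values[1, 1, 1]
  expect_lt(corner, 0.05 * params$dose_prescription_gy)
})

test_that("rasterized GTV volume is close to the analytic ellipsoid volume", {
  params <- phantom_params(grid_shape = c(40L, 40L, 40L),
                           spacing_mm = c(1, 1, 1),
                           gtv_radius_mm = c(8, 0.5), seed = 21)
  for (s in c(21, 22, 23)) {
    rec <- generate_patient(params, "P1", s)
    mask <- rasterize(rec$gtv, rec$ct)
    vox_vol <- sum(mask$values) * prod(rec$ct$spacing_mm)
    nominal <- 4 / 3 * pi * 8^3
    expect_lt(abs(vox_vol - nominal) / nominal, 0.15)
  }
})

test_that("the null cohort matches the target prevalence", {
  params <- tiny_phantom_params(n_patients = 1000L, effect_size = 0,
                                prevalence = 0.302,
                                grid_shape = c(26L, 26L, 14L),
                                gtv_radius_mm = c(5, 0.3), seed = 33)
  # outcome calibration does not need images: draw from the same logistic
  # model the generator uses, with a null effect
  z <- rnorm(1000)
  a <- dosiomics:::calibrate_intercept(z, 0, 0.302)
  expect_equal(stats::plogis(a), 0.302, tolerance = 1e-6)
  set.seed(1)
  ev <- rbinom(1000, 1, stats::plogis(a + 0 * z))
  ci <- binom_ci95(sum(ev), 1000)
  expect_gte(0.302, ci[1])
  expect_lte(0.302, ci[2])
})

test_that("expected event count reproduces the cohort imbalance", {
  z <- rnorm(43)
  a <- dosiomics:::calibrate_intercept(z, 2, 0.302)
  p <- stats::plogis(a + 2 * z)
  expect_equal(sum(p), 43 * 0.302, tolerance = 1e-6)   # 13 expected events
})

test_that("the planted signal separates event from non-event BED variance", {
  params <- tiny_phantom_params(n_patients = 120L, effect_size = 2,
                                grid_shape = c(26L, 26L, 14L),
                                gtv_radius_mm = c(5, 0.3), seed = 55)
  coh <- generate_cohort(params)
  bv <- vapply(coh, function(r) attr(r, "bed_var_gtv"), 1)
  ev <- vapply(coh, `[[`, TRUE, "event")
  expect_gt(mean(bv[ev]), mean(bv[!ev]))
  # events occur before the 36-month horizon, follow-up spans beyond it
  tm <- vapply(coh, `[[`, 1, "time_months")
  expect_true(all(tm[ev] < 36))
  expect_true(all(tm > 0))
})

test_that("cohort generation is a pure function of its parameters", {
  params <- tiny_phantom_params(n_patients = 12L, seed = 9)
  c1 <- generate_cohort(params)
  c2 <- generate_cohort(params)
  expect_identical(c1, c2)
  expect_error(generate_cohort(tiny_phantom_params(n_patients = 5L)),
               "n_patients >= 10")
})
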