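test_that("shape features: unit voxel, digital ball, diameter oracle", {
  one <- roi_mask(array(c(rep(0, 13), 1, rep(0, 13)), c(3, 3, 3)), c(1, 1, 1))
  sf1 <- suppressWarnings(shape_features(one))
  expect_equal(unname(sf1["shape_volume_voxel"]), 1)
  expect_equal(unname(sf1["shape_max_diameter_3d"]), 0)

  ball <- ball_mask(10)
  sf <- shape_features(ball)
  expect_gte(unname(sf["shape_sphericity"]), 0.97)
  expect_lte(unname(sf["shape_sphericity"]), 1.0)
  expect_equal(unname(sf["shape_volume_voxel"]), 4 / 3 * pi * 1000,
               tolerance = 0.05)
  expect_equal(unname(sf["shape_elongation"]), 1, tolerance = 0.05)
  # consistency identities among the mesh-derived descriptors
  expect_equal(unname(sf["shape_sphericity"]),
               unname(sf["shape_compactness2"]^(1 / 3)))
  expect_equal(unname(sf["shape_spherical_disproportion"]),
               unname(1 / sf["shape_sphericity"]))

  # max 3D diameter equals the brute-force pairwise maximum on a small blob
  set.seed(8)
  m <- array(0, c(6, 6, 6))
  m[sample(216, 20)] <- 1
  blob <- roi_mask(m, c(1, 1, 1))
  sfb <- suppressWarnings(shape_features(blob))
  centres <- (which(m == 1, arr.ind = TRUE) - 1)
  dmax <- 0
  for (i in 1:19) for (j in (i + 1):20)
    dmax <- max(dmax, sqrt(sum((centres[i, ] - centres[j, ])^2)))
  expect_equal(unname(sfb["shape_max_diameter_3d"]), dmax)
})

test_that("shape features are invariant to rigid translation of the mask", {
  set.seed(12)
  m <- array(0, c(10, 10, 10))
  m[3:6, 4:7, 3:5] <- rbinom(48, 1, 0.8)
  a <- shape_features(roi_mask(m, c(1, 1, 1)))
  shifted <- array(0, c(10, 10, 10))
  shifted[5:8, 2:5, 5:7] <- m[3:6, 4:7, 3:5]
  b <- shape_features(roi_mask(shifted, c(1, 1, 1)))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("intensity statistics match hand arithmetic and conventions", {
  mk <- function(vals) {
    a <- array(NA_real_, c(length(vals), 1, 1))
    a[, 1, 1] <- vals
    image_volume(a, c(1, 1, 1), unit = "GY")
  }
  s <- intensity_statistics(mk(c(1, 2, 3, 4)))
  expect_equal(unname(s["stat_variance"]), 1.25)   # population form
  expect_equal(unname(s["stat_mean"]), 2.5)
  expect_equal(unname(s["stat_energy"]), 30)
  expect_equal(unname(s["stat_rms"]), sqrt(30 / 4))

  expect_equal(unname(intensity_statistics(mk(c(1, 2)))["stat_energy"]), 5)

  cst <- intensity_statistics(mk(rep(7, 10)))
  expect_equal(unname(cst[c("stat_variance", "stat_skewness",
                            "stat_kurtosis")]), c(0, 0, 0))
  expect_error(intensity_statistics(mk(NA_real_)), "empty")
})

test_that("integrated intensity is mean intensity times ROI volume", {
  a <- array(NA_real_, c(5, 2, 1))
  a[1:5, 1, 1] <- 2
  vol <- image_volume(a, c(1, 1, 2), unit = "BED_GY")
  msk <- roi_mask(array(as.numeric(!is.na(a)), dim(a)), c(1, 1, 2))
  ii <- integrated_intensity(vol, msk)
  expect_equal(unname(ii), 2 * 5 * 2)       # mean 2 x (5 voxels x 2 mm3)
  vol2 <- vol
  vol2$values <- vol$values * 2
  expect_equal(unname(integrated_intensity(vol2, msk)), 2 * unname(ii))
  a0 <- a; a0[!is.na(a0)] <- 0
  expect_equal(unname(integrated_intensity(
    image_volume(a0, c(1, 1, 2), unit = "BED_GY"), msk)), 0)
})

test_that("histogram features: degenerate, fair-coin and random oracle", {
  mk <- function(vals, nlev) {
    a <- array(NA_real_, c(length(vals), 1, 1))
    a[, 1, 1] <- vals
    v <- image_volume(a, c(1, 1, 1), unit = "GREY_LEVEL")
    attr(v, "n_levels") <- as.integer(nlev)
    v
  }
  single <- histogram_features(mk(rep(3, 12), 64))
  expect_equal(unname(single["hist_entropy"]), 0)
  expect_equal(unname(single["hist_uniformity"]), 1)
  expect_equal(unname(single["hist_mode"]), 3)

  coin <- histogram_features(mk(rep(c(2, 5), 10), 8))
  expect_equal(unname(coin["hist_entropy"]), 1)
  expect_equal(unname(coin["hist_uniformity"]), 0.5)
  expect_equal(unname(coin["hist_mode"]), 2)   # lowest level on ties

  # random ROI vs a direct tally oracle
  set.seed(31)
  g <- sample.int(16, 100, replace = TRUE)
  got <- histogram_features(mk(g, 16))
  counts <- sapply(1:16, function(l) sum(g == l))
  p <- counts / 100
  expect_equal(unname(got["hist_mean"]), mean(g))
  expect_equal(unname(got["hist_variance"]), mean((g - mean(g))^2))
  expect_equal(unname(got["hist_median"]), median(g))
  expect_equal(unname(got["hist_mode"]), which.max(counts))
  expect_equal(unname(got["hist_entropy"]), -sum(p[p > 0] * log2(p[p > 0])))
  expect_equal(unname(got["hist_uniformity"]), sum(p^2))
  grad <- c(counts[2] - counts[1],
            (counts[3:16] - counts[1:14]) / 2,
            counts[16] - counts[15])
  expect_equal(unname(got["hist_max_gradient"]), max(grad))
  expect_equal(unname(got["hist_max_gradient_level"]), which.max(grad))
  expect_equal(unname(got["hist_min_gradient"]), min(grad))
  expect_equal(unname(got["hist_min_gradient_level"]), which.min(grad))
  q <- quantile(g, c(.1, .25, .5, .75, .9), names = FALSE)
  expect_equal(unname(got["hist_p10"]), q[1])
  expect_equal(unname(got["hist_iqr"]), q[4] - q[2])
  expect_equal(unname(got["hist_qcod"]), (q[4] - q[2]) / (q[4] + q[2]))
  expect_equal(unname(got["hist_median_ad"]), mean(abs(g - median(g))))
  inband <- g[g >= q[1] & g <= q[5]]
  expect_equal(unname(got["hist_robust_mad"]),
               mean(abs(inband - mean(inband))))
})

test_that("the catalogue closes at 380 uniquely named features", {
  cat380 <- feature_catalogue()
  expect_equal(nrow(cat380), 380L)
  expect_false(anyDuplicated(cat380$name) > 0)
  expect_equal(sum(cat380$family == "SHAPE"), 17L)
  expect_equal(unname(table(cat380$modality)[c("CT", "PET", "BED")]),
               rep(121L, 3), ignore_attr = TRUE)
  # the four headline predictors exist as BED columns
  expect_true(all(c("BED_stat_variance", "BED_stat_energy",
                    "BED_integrated_intensity", "BED_glszm_lzhge") %in%
                    cat380$name))
})

test_that("extract_all is deterministic and invariant to voxel storage order", {
  params <- tiny_phantom_params(seed = 19)
  rec <- generate_patient(params, "P1", 19)
  pre <- preprocess_patient(rec)
  f1 <- extract_all(pre)
  f2 <- extract_all(pre)
  expect_identical(f1, f2)
  expect_equal(length(f1), 380L)
  expect_true(all(is.finite(f1)))
  expect_identical(names(f1), feature_catalogue()$name)

  pre_missing <- pre
  pre_missing$bed <- NULL
  expect_error(extract_all(pre_missing), "missing")
})
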