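test_that("SUV conversion applies the body-weight decay-corrected formula", {
  pet <- image_volume(array(1000, c(2, 2, 2)), c(1, 1, 1), unit = "BQ_ML")
  suv <- to_suv(pet, body_weight_g = 70000, injected_activity_bq = 7e7,
                delay_s = 0, half_life_s = 6586)
  expect_equal(suv$values[1], 1.0)
  expect_identical(suv$unit, "SUV")

  # waiting one half-life doubles SUV relative to no delay
  suv2 <- to_suv(pet, 70000, 7e7, delay_s = 6586, half_life_s = 6586)
  expect_equal(suv2$values[1], 2 * suv$values[1])

  # random volume against a voxel-by-voxel loop oracle
  set.seed(4)
  vals <- array(runif(27, 0, 5000), c(3, 3, 3))
  pet3 <- image_volume(vals, c(2, 2, 2), unit = "BQ_ML")
  suv3 <- to_suv(pet3, 81000, 3.2e8, 1800, 1223.4)
  oracle <- array(NA_real_, dim(vals))
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    oracle[i, j, k] <- vals[i, j, k] * 81000 / (3.2e8 * 2^(-1800 / 1223.4))
  expect_equal(suv3$values, oracle)

  expect_error(to_suv(pet, -1, 7e7, 0, 6586), "positive")
})

test_that("BED conversion reproduces the linear-quadratic closed form", {
  mk <- function(d, n) dose_grid(image_volume(array(d, c(2, 2, 2)),
                                              c(1, 1, 1), unit = "GY"), n)
  expect_equal(round(to_bed(mk(35, 7), 1.5)$values[1], 1), 151.7)
  expect_equal(to_bed(mk(0, 7), 1.5)$values[1], 0)
  expect_equal(to_bed(mk(14, 7), 1.5)$values[1], 14 * (1 + 2 / 1.5))
  expect_error(to_bed(mk(10, 5), 0), "alpha_beta")
})

test_that("crossing-number test agrees with a winding-number oracle", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_true(point_in_polygon(c(0.5, 0.5), square))
  expect_false(point_in_polygon(c(2, 0.5), square))

  # concave 10-gon vs independent winding oracle at 200 random points
  set.seed(11)
  theta <- sort(runif(10, 0, 2 * pi))
  rad <- runif(10, 0.4, 1.6)         # wildly varying radius -> concave
  poly <- cbind(rad * cos(theta), rad * sin(theta))
  pts <- matrix(runif(400, -2, 2), ncol = 2)
  got <- apply(pts, 1, point_in_polygon, polygon = poly)
  want <- apply(pts, 1, pip_winding_oracle, polygon = poly)
  expect_identical(got, want)

  degen <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_warning(res <- point_in_polygon(c(1, 0), degen), "degenerate")
  expect_false(res)
})

test_that("rasterization counts voxel centres inside per-slice polygons", {
  ref <- image_volume(array(0, c(12, 12, 3)), c(1, 1, 1), unit = "HU")
  # square strictly covering the 5x5 block of centres at x,y = 2..6 mm
  sq <- rbind(c(1.5, 1.5), c(6.5, 1.5), c(6.5, 6.5), c(1.5, 6.5))
  cs <- contour_set("GTV", list(list(z_mm = 1, vertices = sq)))
  m <- rasterize(cs, ref)
  expect_equal(sum(m$values), 25)
  expect_equal(sum(m$values[, , c(1, 3)]), 0)

  empty <- contour_set("GTV", list())
  expect_equal(sum(rasterize(empty, ref)$values), 0)

  off <- contour_set("GTV", list(list(z_mm = 40, vertices = sq)))
  expect_error(rasterize(off, ref), "outside")
})

test_that("trilinear resampling matches the 8-corner oracle and never overshoots", {
  # identity resampling returns the object untouched
  v0 <- image_volume(array(rnorm(27), c(3, 3, 3)), c(1, 1, 1), unit = "HU")
  expect_identical(resample_trilinear(v0, c(1, 1, 1)), v0)

  # midpoint between 0 and 10 along one axis is 5
  ramp <- image_volume(array(rep(c(0, 10), each = 1, times = 4), c(2, 2, 2)),
                       c(2, 2, 2), unit = "GY")
  out <- resample_trilinear(ramp, c(1, 2, 2))
  expect_equal(out$values[2, 1, 1], 5)

  # random volume vs brute-force oracle at 50 interior points
  set.seed(21)
  v6 <- image_volume(array(runif(216), c(6, 6, 6)), c(1.3, 0.9, 2.1),
                     unit = "HU")
  res <- resample_trilinear(v6, c(0.7, 0.7, 0.7))
  pick <- cbind(sample(2:8, 50, TRUE), sample(2:6, 50, TRUE),
                sample(2:12, 50, TRUE))
  for (r in sample(nrow(pick), 50)) {
    idx <- pick[r, ]
    pt <- v6$origin_mm + (idx - 1) * 0.7
    expect_equal(res$values[idx[1], idx[2], idx[3]],
                 trilinear_oracle(v6, pt), tolerance = 1e-12)
  }
  expect_gte(min(res$values), min(v6$values))
  expect_lte(max(res$values), max(v6$values))

  expect_error(resample_trilinear(v6, c(100, 100, 100)), "extent")
})

test_that("mask resampling binarizes the interpolated field at the threshold", {
  m <- roi_mask(array(c(rep(0, 4), rep(1, 4)), c(2, 2, 2)), c(2, 2, 2))
  out <- resample_mask(m, c(1, 1, 1), threshold = 0.5)
  expect_true(all(out$values %in% c(0, 1)))
  # fractional values at the transition become 1 exactly when >= 0.5
  vol <- image_volume(m$values, m$spacing_mm, m$origin_mm, "GREY_LEVEL")
  ref <- resample_trilinear(vol, c(1, 1, 1))
  expect_equal(out$values, array(as.numeric(ref$values >= 0.5),
                                 dim(ref$values)))
})

test_that("CT rounding is nearest-integer with ties away from zero", {
  ct <- image_volume(array(c(39.6, -0.5, 0.5, 2, -39.6, 1.5, -1.5, 0),
                           c(2, 2, 2)), c(1, 1, 1), unit = "HU")
  out <- round_ct(ct)
  expect_equal(as.vector(out$values), c(40, -1, 1, 2, -40, 2, -2, 0))
  expect_identical(round_ct(out)$values, out$values)  # idempotent
})

test_that("ROI isolation replaces exactly the outside voxels", {
  vol <- image_volume(array(rnorm(27), c(3, 3, 3)), c(1, 1, 1), unit = "HU")
  ones <- roi_mask(array(1, c(3, 3, 3)), c(1, 1, 1))
  expect_identical(apply_roi(vol, ones)$values, vol$values)
  zeros <- roi_mask(array(0, c(3, 3, 3)), c(1, 1, 1))
  expect_true(all(is.na(apply_roi(vol, zeros)$values)))
  set.seed(3)
  m <- roi_mask(array(rbinom(27, 1, 0.5), c(3, 3, 3)), c(1, 1, 1))
  out <- apply_roi(vol, m)
  expect_equal(sum(!is.na(out$values)), sum(m$values))
  bad <- roi_mask(array(1, c(2, 2, 2)), c(1, 1, 1))
  expect_error(apply_roi(vol, bad), "geometr")
})

test_that("fixed-bin-number discretization maps edges, clamps, and is affine-invariant", {
  mk <- function(vals) {
    a <- array(NA_real_, c(length(vals), 1, 1))
    a[, 1, 1] <- vals
    image_volume(a, c(1, 1, 1), unit = "GY")
  }
  d <- discretize_fbn(mk(c(0, 0.5, 1)), 4)
  expect_equal(as.vector(d$values), c(1, 3, 4))
  expect_equal(attr(d, "n_levels"), 4L)

  const <- discretize_fbn(mk(c(2, 2, 2)), 64)
  expect_true(all(const$values == 1))

  set.seed(9)
  x <- runif(40)
  base <- discretize_fbn(mk(x), 64)$values
  resc <- discretize_fbn(mk(3.7 * x + 11), 64)$values
  expect_equal(base, resc)

  expect_error(discretize_fbn(mk(rep(NA_real_, 3)), 64), "empty")
})

test_that("fixed-threshold PET segmentation keeps the peak's connected component", {
  a <- array(1, c(7, 7, 3))
  a[2, 2, 2] <- 10                      # peak blob
  a[2, 3, 2] <- 6
  a[6, 6, 2] <- 7                       # disjoint second blob above 40%
  pet <- image_volume(a, c(1, 1, 1), unit = "SUV")
  region <- roi_mask(array(1, dim(a)), c(1, 1, 1))
  seg <- segment_pet_fixed_threshold(pet, region, 0.40)
  expect_equal(which(seg$values == 1),
               which(a >= 4 & !(a == 7))[c(1, 2)])
  expect_equal(sum(seg$values), 2)      # only the blob holding the max

  seg1 <- segment_pet_fixed_threshold(pet, region, fraction = 0.9999)
  expect_equal(which(seg1$values == 1), which(a == 10))

  flat <- image_volume(array(2, c(3, 3, 3)), c(1, 1, 1), unit = "SUV")
  fr <- roi_mask(array(1, c(3, 3, 3)), c(1, 1, 1))
  expect_warning(sg <- segment_pet_fixed_threshold(flat, fr), "constant")
  expect_equal(sum(sg$values), 27)
})

test_that("the full preprocessing chain produces consistent masked bundles", {
  params <- tiny_phantom_params(seed = 5)
  rec <- generate_patient(params, "P001", 5)
  pre <- preprocess_patient(rec)
  expect_equal(pre$spacing_mm, c(1, 1, 1))
  expect_identical(dim(pre$ct$values), dim(pre$mask$values))
  inside <- pre$mask$values >= 0.5
  expect_gt(sum(inside), 100)
  for (nm in c("ct", "suv", "bed", "ct_d", "suv_d", "bed_d")) {
    expect_true(all(is.na(pre[[nm]]$values[!inside])), info = nm)
    expect_true(all(!is.na(pre[[nm]]$values[inside])), info = nm)
  }
  expect_true(all(pre$ct$values[inside] == round(pre$ct$values[inside])))
  expect_true(all(pre$bed_d$values[inside] %in% 1:64))
})
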