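# Small fixtures built in code at test time.

# compact phantom parameters that keep per-patient volumes tiny
tiny_phantom_params <- function(...) {
  args <- list(grid_shape = c(32L, 32L, 18L),
               spacing_mm = c(1.5, 1.5, 2.5),
               gtv_radius_mm = c(6, 0.4))
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_params, args)
}

# random discretized ROI on a small grid: levels 1..nlev with NA border
random_roi_levels <- function(dims, nlev, na_frac = 0.2, seed = 1) {
  set.seed(seed)
  v <- array(sample.int(nlev, prod(dims), replace = TRUE), dims)
  v[runif(prod(dims)) < na_frac] <- NA
  if (all(is.na(v))) v[1, 1, 1] <- 1L
  v
}

as_grey_volume <- function(arr, n_levels, spacing = c(1, 1, 1)) {
  vol <- image_volume(array(as.numeric(arr), dim(arr)), spacing,
                      unit = "GREY_LEVEL")
  attr(vol, "n_levels") <- as.integer(n_levels)
  vol
}

# digital ball mask
ball_mask <- function(r, spacing = c(1, 1, 1), pad = 3) {
  n <- ceiling(2 * r / spacing) + 2 * pad
  cc <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n[1]), y = seq_len(n[2]), z = seq_len(n[3]))
  inside <- ((g$x - cc[1]) * spacing[1])^2 + ((g$y - cc[2]) * spacing[2])^2 +
    ((g$z - cc[3]) * spacing[3])^2 <= r^2
  roi_mask(array(as.numeric(inside), n), spacing)
}
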