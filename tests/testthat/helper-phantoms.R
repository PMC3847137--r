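# Shared fixtures: compact phantom specs and brute-force oracles.

# small thoracic phantom for fast tests
small_spec <- function(seed = 1L, ...) {
  thoracic_phantom_spec(grid_shape = c(6, 96, 96), seed = seed, ...)
}

# calibration-style phantom pair: MR fat uniform just above mu + 10.5 sigma,
# partial-volume rim (non-fat on CT) spanning mu + 4.5..10.2 sigma so every
# k < 10 incurs rim false positives while k > 10 loses fat; generous
# reference sampling keeps the estimated threshold tight. The Dice-vs-k
# curve then peaks at the construction multiplier k = 10.
calib_spec <- function(seed = 1L) {
  thoracic_phantom_spec(
    grid_shape = c(8, 96, 96), seed = seed,
    muscle_mean = 100, muscle_sd = 5,
    rois_per_slice = 6, roi_diameter_mm = 10,
    fat_signal_range = 100 + c(10.5, 11.5) * 5,
    rim_thickness_px = 2, rim_signal_range = 100 + c(4.5, 10.2) * 5)
}

# LV phantom with noise negligible relative to the 5-SD threshold
quiet_lv <- function(scar_fraction, seed = 1L, ...)
  make_lv_phantom(scar_fraction, remote_mean = 100, remote_sd = 2,
                  scar_mean = 600, seed = seed, ...)

# brute-force per-voxel volumetry oracle: loop over every voxel, apply the
# contour-membership + threshold rule directly
bf_itfv_ml <- function(grid, contours, threshold) {
  d <- dim(grid$values)
  slice_of <- integer(0)
  region <- array(FALSE, d)
  for (ct in contours) region <- region | rasterize_contour(ct, d)$values
  count <- 0L
  for (s in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3]))
    if (region[s, i, j] && grid$values[s, i, j] >= threshold)
      count <- count + 1L
  count * (prod(grid$pixel_spacing_mm) * slice_spacing(grid)) / 1000
}

# random star-shaped polygon around a center; jittered evenly spaced angles
# keep every angular gap below pi, which guarantees simplicity
random_star_polygon <- function(slice, center, n_vertices, r_min, r_max) {
  spacing <- 2 * pi / n_vertices
  th <- sort((seq_len(n_vertices) + stats::runif(n_vertices, -0.45, 0.45)) *
               spacing + stats::runif(1, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_min, r_max)
  planar_contour(slice, cbind(center[1] + r * sin(th), center[2] + r * cos(th)))
}

# mean of a normal truncated below at 0 (resampling truncation target)
truncnorm_mean0 <- function(mu, sigma) {
  if (sigma == 0) return(mu)
  a <- mu / sigma
  mu + sigma * stats::dnorm(a) / stats::pnorm(a)
}
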