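test_that("reference statistics pool ROI pixels with the n-1 SD", {
  g <- voxel_grid(array(100, c(1, 30, 30)), pixel_spacing_mm = c(1.6, 1.6))
  roi <- circular_roi(1, c(15, 15), 8)
  s <- reference_stats(g, list(roi))
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 0)
  expect_equal(s$n_rois, 1L)

  # two single-pixel ROIs with pooled values {98, 102}
  g$values[1, 5, 5] <- 98
  g$values[1, 25, 25] <- 102
  tiny <- function(r, c) circular_roi(1, c(r, c), 1, diameter_limits = c(0.5, 10))
  s2 <- reference_stats(g, list(tiny(5, 5), tiny(25, 25)))
  expect_equal(s2$mean, 100)
  expect_equal(s2$sd, sqrt(8), tolerance = 1e-12)  # 2.828 with n-1 denominator
  expect_equal(s2$n_pixels, 2L)

  expect_error(reference_stats(g, list()), "empty")
  expect_error(reference_stats(g, list(tiny(5, 5))), "fewer than 2")
})

test_that("reference statistics recover the muscle distribution on phantoms", {
  b <- make_thoracic_phantom(small_spec(seed = 31))
  s <- reference_stats(b$mr, b$muscle_rois)
  expect_gt(s$n_pixels, 500)
  expect_true(s$mean > 98 && s$mean < 102)
  expect_true(s$sd > 4 && s$sd < 6)
})

test_that("fat_threshold is mean + k * sd", {
  st <- structure(list(mean = 100, sd = 5, n_pixels = 10L, n_rois = 1L),
                  class = "reference_stats")
  expect_equal(fat_threshold(st, 10), 150)
  expect_equal(fat_threshold(st, 5), 125)
  st0 <- structure(list(mean = 80, sd = 0, n_pixels = 10L, n_rois = 1L),
                  class = "reference_stats")
  expect_equal(fat_threshold(st0, 10), 80)
  st2 <- structure(list(mean = 80, sd = 3.5, n_pixels = 10L, n_rois = 1L),
                  class = "reference_stats")
  expect_equal(fat_threshold(st2, 5), 97.5)
  expect_error(fat_threshold(st, 0), "> 0")
})

test_that("segmentation applies the inclusive threshold inside the contour", {
  vals <- array(10, c(2, 8, 8))
  vals[1, 3, 3] <- 150      # exactly at threshold: included
  vals[1, 3, 4] <- 149.999  # just below: excluded
  vals[1, 1, 1] <- 500      # outside contour: excluded
  g <- voxel_grid(vals, pixel_spacing_mm = c(1, 1))
  ct <- planar_contour(1, rbind(c(1.5, 1.5), c(1.5, 6.5), c(6.5, 6.5), c(6.5, 1.5)))
  expect_warning(m <- segment_fat(g, list(ct), 150), "slice")
  expect_equal(sum(m$values), 1)
  expect_true(m$values[1, 3, 3])

  # threshold above the global maximum gives an empty mask
  expect_warning(m2 <- segment_fat(g, list(ct), 1000), "slice")
  expect_false(any(m2$values))

  ctg <- voxel_grid(array(-100, c(1, 4, 4)), modality = "CT")
  expect_error(segment_fat(ctg, list(), 0), "MR")
})

test_that("noise-free phantom segmentation equals the generator truth exactly", {
  b <- make_thoracic_phantom(small_spec(seed = 4, muscle_sd = 0, fat_sd = 0,
                                        background_sd = 0))
  m <- segment_fat(b$mr, b$thoracic_contours, 150)
  expect_identical(m$values, b$fat_truth$values)
})

test_that("slice-summation volumetry follows area x effective spacing", {
  g <- voxel_grid(array(0, c(3, 40, 40)), pixel_spacing_mm = c(1.6, 1.6),
                  slice_thickness_mm = 8, slice_gap_mm = 2)
  m <- array(FALSE, c(3, 40, 40))
  expect_equal(itfv(binary_mask(m), g), 0)
  m[1, 1:25, 1:40] <- TRUE  # 1000 pixels on one slice
  expect_equal(itfv(binary_mask(m), g), 25.6)  # 1000 x 2.56 mm^2 x 10 mm
  m[2, 1:25, 1:40] <- TRUE  # equal area on a second slice: exactly doubles
  expect_equal(itfv(binary_mask(m), g), 51.2)
  # thickness-only integration drops the gap contribution
  expect_equal(itfv(binary_mask(m), g, integration = "thickness"), 51.2 * 0.8)
  expect_error(itfv(binary_mask(array(FALSE, c(2, 40, 40))), g), "mismatch")
})

test_that("volume is monotone non-increasing in the threshold", {
  b <- make_thoracic_phantom(small_spec(seed = 6))
  vols <- vapply(seq(50, 250, by = 20), function(thr)
    itfv(segment_fat(b$mr, b$thoracic_contours, thr), b$mr), 1.0)
  expect_true(all(diff(vols) <= 0))
})

test_that("segmentation plus volumetry agrees with the brute-force voxel loop", {
  sp <- thoracic_phantom_spec(
    grid_shape = c(3, 48, 48), seed = 8,
    fat_regions = list(list(center = c(10, 35, 35), semi_axes = c(9, 12, 12))))
  b <- make_thoracic_phantom(sp)
  stats <- reference_stats(b$mr, b$muscle_rois)
  thr <- fat_threshold(stats, 10)
  fast <- itfv(segment_fat(b$mr, b$thoracic_contours, thr), b$mr)
  expect_identical(fast, bf_itfv_ml(b$mr, b$thoracic_contours, thr))
})

test_that("BMI indexing is volume / BMI and inverts the cohort construction", {
  expect_equal(index_itfv(600, 30), 20)
  expect_equal(index_itfv(0, 25), 0)
  expect_error(index_itfv(100, 0), "BMI")
  co <- simulate_cohort(cohort_spec(seed = 3))
  expect_equal(index_itfv(co$itfv_ml, co$bmi), co$indexed_itfv)
})

test_that("quantify_itfv assembles threshold, areas, volume and indexing", {
  b <- make_thoracic_phantom(small_spec(seed = 13))
  res <- quantify_itfv(b$mr, b$thoracic_contours, b$muscle_rois, k = 10, bmi = 28)
  expect_s3_class(res, "itfv_result")
  expect_equal(res$volume_ml, itfv(res$mask, b$mr))
  expect_equal(res$indexed_volume, res$volume_ml / 28)
  expect_length(res$per_slice_area_mm2, dim(b$mr$values)[1])
  expect_equal(sum(res$per_slice_area_mm2) * slice_spacing(b$mr) / 1000,
               res$volume_ml)
})
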