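test_that("voxel_grid enforces its invariants", {
  expect_error(voxel_grid(matrix(1, 2, 2)), "3-D")
  expect_error(voxel_grid(array(numeric(0), c(0, 2, 2))), "empty")
  expect_error(voxel_grid(array(-1, c(2, 2, 2)), modality = "MR"), "non-negative")
  expect_silent(voxel_grid(array(-500, c(2, 2, 2)), modality = "CT"))
  expect_error(voxel_grid(array(1, c(2, 2, 2)), pixel_spacing_mm = c(0, 1)), "positive")
  expect_error(voxel_grid(array(NA_real_, c(2, 2, 2))), "finite")
  g <- voxel_grid(array(1, c(3, 4, 5)), slice_thickness_mm = 8, slice_gap_mm = 2)
  expect_equal(slice_spacing(g), 10)
  expect_equal(voxel_volume_mm3(g), 1.6 * 1.6 * 10)
})

test_that("NIfTI round trip preserves values and spacings exactly", {
  vals <- array(as.numeric(sample.int(1000, 3 * 10 * 10, replace = TRUE)),
                c(3, 10, 10))
  g <- voxel_grid(vals, pixel_spacing_mm = c(1.6, 1.6),
                  slice_thickness_mm = 8, slice_gap_mm = 2)
  path <- file.path(tempdir(), "rt.nii.gz")
  write_volume(g, path)
  g2 <- read_volume(path)
  expect_identical(g2$values, g$values)
  expect_equal(g2$pixel_spacing_mm, g$pixel_spacing_mm)
  expect_equal(g2$slice_thickness_mm, 8)
  expect_equal(g2$slice_gap_mm, 2)
  expect_equal(g2$modality, "MR")
  # the stored slice zoom is the effective spacing thickness + gap = 10;
  # verified through an independent NIfTI reader
  hdr <- oro.nifti::readNIfTI(path)
  expect_equal(oro.nifti::pixdim(hdr)[2:4], c(10, 1.6, 1.6), tolerance = 1e-6)
})

test_that("read_volume rejects missing files and non-3-D images", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "missing")
  p2 <- file.path(tempdir(), "flat.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(1, 4, 4)), p2)
  expect_error(read_volume(p2, modality = "MR"), "non-3-D")
})

test_that("planar_contour rejects degenerate polygons", {
  expect_error(planar_contour(1, rbind(c(1, 1), c(2, 2))), "n >= 3")
  # bow-tie self-intersection
  expect_error(planar_contour(1, rbind(c(1, 1), c(5, 5), c(1, 5), c(5, 1))),
               "self-intersect")
  expect_error(planar_contour(1, rbind(c(1, 1), c(1, 5), c(1, 9))), "zero area")
})

test_that("rasterization marks exactly the pixels with centers inside", {
  # interchange example: 0-based square (0.5,0.5)-(4.5,4.5) on a 10x10 slice
  # encloses the 16 centers (1..4, 1..4)
  path <- file.path(tempdir(), "sq.json")
  jsonlite::write_json(
    list(list(slice = 0L,
              vertices = list(c(0.5, 0.5), c(0.5, 4.5), c(4.5, 4.5), c(4.5, 0.5)))),
    path, auto_unbox = TRUE)
  sq <- read_contours(path)[[1]]
  m <- rasterize_contour(sq, c(1, 10, 10))
  expect_equal(sum(m$values), 16)
  expect_true(all(which(m$values[1, , ], arr.ind = TRUE) >= 2 &
                  which(m$values[1, , ], arr.ind = TRUE) <= 5))

  # full-frame rectangle saturates the slice
  full <- planar_contour(2, rbind(c(0.5, 0.5), c(0.5, 10.5),
                                  c(10.5, 10.5), c(10.5, 0.5)))
  mf <- rasterize_contour(full, c(3, 10, 10))
  expect_equal(sum(mf$values[2, , ]), 100)
  expect_equal(sum(mf$values), 100)  # only that slice

  # polygon outside the grid footprint errors
  tri <- planar_contour(1, rbind(c(20, 20), c(25, 20), c(22, 25)))
  expect_error(rasterize_contour(tri, c(1, 10, 10)), "out-of-bounds")
})

test_that("rasterization is orientation-independent and matches an independent oracle", {
  skip_if_not_installed("pracma")
  set.seed(42)
  for (rep in 1:15) {
    shape <- c(1, sample(16:64, 1), sample(16:64, 1))
    ctr <- c(stats::runif(1, 8, shape[2] - 7), stats::runif(1, 8, shape[3] - 7))
    rmax <- min(ctr[1] - 1, ctr[2] - 1, shape[2] - ctr[1], shape[3] - ctr[2])
    poly <- random_star_polygon(1, ctr, sample(5:12, 1), 0.3 * rmax, rmax)
    m <- rasterize_contour(poly, shape)
    rev_poly <- planar_contour(1, poly$vertices[rev(seq_len(nrow(poly$vertices))), ])
    expect_identical(rasterize_contour(rev_poly, shape)$values, m$values)
    pts <- expand.grid(row = seq_len(shape[2]), col = seq_len(shape[3]))
    oracle <- pracma::inpolygon(pts$row, pts$col,
                                poly$vertices[, 1], poly$vertices[, 2],
                                boundary = FALSE)
    expect_identical(as.vector(m$values[1, , ]),
                     as.vector(matrix(oracle, shape[2], shape[3])))
  }
})

test_that("roi_pixels selects by physical distance", {
  vals <- array(100, c(2, 40, 40))
  g <- voxel_grid(vals, pixel_spacing_mm = c(1.6, 1.6))
  # constant field: every returned value is 100
  roi <- circular_roi(1, c(20, 20), 8)
  expect_true(all(roi_pixels(roi, g) == 100))
  # 8 mm disc on 1.6 mm pixels: matches the exhaustive distance test
  n_oracle <- 0L
  for (i in 1:40) for (j in 1:40)
    if (((i - 20) * 1.6)^2 + ((j - 20) * 1.6)^2 <= 4^2) n_oracle <- n_oracle + 1L
  expect_length(roi_pixels(roi, g), n_oracle)
  # sub-pixel disc centered on a pixel returns that single pixel
  g$values[1, 10, 10] <- 77
  tiny <- circular_roi(1, c(10, 10), 1, diameter_limits = c(0.5, 10))
  expect_equal(roi_pixels(tiny, g), 77)
  # disc extending beyond the image errors
  expect_error(roi_pixels(circular_roi(1, c(2, 2), 8), g), "beyond")
  # default diameter limits reflect the 5-10 mm protocol
  expect_error(circular_roi(1, c(20, 20), 3), "range")
})

test_that("contour and ROI JSON interchange round-trips (0-based on disk)", {
  ct <- planar_contour(3, rbind(c(2.5, 3.5), c(2.5, 9.5), c(8.5, 9.5), c(8.5, 3.5)))
  roi <- circular_roi(2, c(7.25, 8.5), 6.5)
  pc <- file.path(tempdir(), "contours.json")
  pr <- file.path(tempdir(), "rois.json")
  write_contours(list(ct), pc)
  write_rois(list(roi), pr)
  raw <- jsonlite::read_json(pc, simplifyVector = TRUE)
  expect_equal(raw$slice[[1]], 2)  # 0-based on disk
  ct2 <- read_contours(pc)[[1]]
  roi2 <- read_rois(pr)[[1]]
  expect_equal(ct2$slice_index, 3L)
  expect_equal(ct2$vertices, ct$vertices)
  expect_equal(roi2$center, roi$center)
  expect_equal(roi2$diameter_mm, roi$diameter_mm)
})
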