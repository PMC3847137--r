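# Synthetic ground-truth generators: paired MR/CT thoracic phantoms, LV LGE
# phantoms and four-group cohorts. These are first-class, tested code: every
# downstream stage of the package is exercised against their known truth.

# draw n values from N(mean, sd), redrawing negatives (truncation by
# resampling keeps the bulk approximately normal instead of piling mass at 0)
.rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:1000) {
    bad <- which(x < 0)
    if (!length(bad)) return(x)
    x[bad] <- stats::rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
  }
  stop("truncation resampling failed to converge; distribution mass is almost entirely negative")
}

#' Specification of a paired MR/CT thoracic phantom
#'
#' Describes a sagittal fat-bright MR stack and a co-registered CT stack
#' with three compartments: low-signal interior/background tissue, a
#' posterior paravertebral muscle band lying outside the traced
#' intra-thoracic contour (where the reference ROIs are placed), and
#' ellipsoidal fat deposits inside the contour. MR compartments are
#' Gaussian; CT values are uniform within the conventional Hounsfield
#' ranges (fat -190..-30 HU by default, air -1000 HU).
#'
#' Optional constructs for threshold-calibration experiments:
#' `fat_signal_range` draws MR fat uniformly in a signal window instead of
#' a Gaussian, and `rim_thickness_px`/`rim_signal_range` add a
#' partial-volume shell around each fat deposit whose MR signal is
#' intermediate but which is non-fat on CT.
#'
#' @param grid_shape (slices, rows, cols).
#' @param pixel_spacing_mm in-plane (row, col) spacing, mm.
#' @param slice_thickness_mm,slice_gap_mm acquisition geometry, mm.
#' @param muscle_mean,muscle_sd,fat_mean,fat_sd,background_mean,background_sd
#'   MR compartment distributions (signal units).
#' @param fat_regions list of ellipsoids, each
#'   `list(center = c(z, r, c), semi_axes = c(a, b, c))` in mm (pixel 1 /
#'   slice 1 sits at 0 mm on each axis). `NULL` gives two default deposits.
#' @param thoracic_contour_margin_px inset of the rectangular intra-thoracic
#'   contour from the image border, pixels.
#' @param rois_per_slice,roi_diameter_mm muscle reference ROIs per slice.
#' @param ct_fat_hu_range,ct_muscle_hu_range,ct_air_hu CT compartments, HU.
#' @param fat_signal_range optional (low, high): uniform MR fat signal.
#' @param rim_thickness_px partial-volume shell thickness (0 = none).
#' @param rim_signal_range (low, high) uniform MR signal of the shell.
#' @param seed RNG seed.
#' @return An object of class `thoracic_phantom_spec`.
#' @export
thoracic_phantom_spec <- function(grid_shape = c(8, 128, 128),
                                  pixel_spacing_mm = c(1.6, 1.6),
                                  slice_thickness_mm = 8, slice_gap_mm = 2,
                                  muscle_mean = 100, muscle_sd = 5,
                                  fat_mean = 200, fat_sd = 10,
                                  background_mean = 20, background_sd = 5,
                                  fat_regions = NULL,
                                  thoracic_contour_margin_px = 12,
                                  rois_per_slice = 5, roi_diameter_mm = 8,
                                  ct_fat_hu_range = c(-190, -30),
                                  ct_muscle_hu_range = c(35, 55),
                                  ct_air_hu = -1000,
                                  fat_signal_range = NULL,
                                  rim_thickness_px = 0,
                                  rim_signal_range = NULL,
                                  seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  if (any(c(muscle_sd, fat_sd, background_sd) < 0)) stop("all SDs must be >= 0")
  if (fat_mean <= muscle_mean) stop("fat_mean must exceed muscle_mean (fat is bright on HASTE)")
  if (ct_fat_hu_range[1] >= ct_fat_hu_range[2]) stop("bad CT fat window")
  if (rim_thickness_px > 0 && is.null(rim_signal_range))
    stop("rim_signal_range required when rim_thickness_px > 0")
  if (is.null(fat_regions)) {
    ext <- .phantom_extent_mm(grid_shape, pixel_spacing_mm,
                              slice_thickness_mm + slice_gap_mm)
    fat_regions <- list(
      list(center = c(0.5 * ext[1], 0.40 * ext[2], 0.40 * ext[3]),
           semi_axes = c(0.30 * ext[1], 30, 25)),
      list(center = c(0.5 * ext[1], 0.68 * ext[2], 0.58 * ext[3]),
           semi_axes = c(0.22 * ext[1], 18, 16)))
  }
  spec <- structure(
    list(grid_shape = grid_shape, pixel_spacing_mm = pixel_spacing_mm,
         slice_thickness_mm = slice_thickness_mm, slice_gap_mm = slice_gap_mm,
         muscle_mean = muscle_mean, muscle_sd = muscle_sd,
         fat_mean = fat_mean, fat_sd = fat_sd,
         background_mean = background_mean, background_sd = background_sd,
         fat_regions = fat_regions,
         thoracic_contour_margin_px = as.integer(thoracic_contour_margin_px),
         rois_per_slice = as.integer(rois_per_slice),
         roi_diameter_mm = roi_diameter_mm,
         ct_fat_hu_range = ct_fat_hu_range,
         ct_muscle_hu_range = ct_muscle_hu_range, ct_air_hu = ct_air_hu,
         fat_signal_range = fat_signal_range,
         rim_thickness_px = rim_thickness_px,
         rim_signal_range = rim_signal_range,
         seed = as.integer(seed)),
    class = "thoracic_phantom_spec")
  .validate_fat_regions(spec)
  spec
}

.phantom_extent_mm <- function(grid_shape, sp, slice_sp)
  c((grid_shape[1] - 1) * slice_sp, (grid_shape[2] - 1) * sp[1],
    (grid_shape[3] - 1) * sp[2])

# ellipsoids must lie inside the traced contour (in-plane) with a safety
# margin for the rim shell
.validate_fat_regions <- function(spec) {
  m <- spec$thoracic_contour_margin_px
  sp <- spec$pixel_spacing_mm
  d <- spec$grid_shape
  pad <- spec$rim_thickness_px * max(sp)
  lo_r <- m * sp[1]; hi_r <- (d[2] - m - 1) * sp[1]
  lo_c <- m * sp[2]; hi_c <- (d[3] - m - 1) * sp[2]
  for (e in spec$fat_regions) {
    if (e$center[2] - e$semi_axes[2] - pad < lo_r ||
        e$center[2] + e$semi_axes[2] + pad > hi_r ||
        e$center[3] - e$semi_axes[3] - pad < lo_c ||
        e$center[3] + e$semi_axes[3] + pad > hi_c)
      stop("fat ellipsoid extends outside the thoracic contour")
  }
  invisible(TRUE)
}

# logical 3-D array of voxels inside an ellipsoid (centers, physical mm)
.ellipsoid_mask <- function(grid_shape, sp, slice_sp, center, semi) {
  z <- (seq_len(grid_shape[1]) - 1) * slice_sp
  r <- (seq_len(grid_shape[2]) - 1) * sp[1]
  cc <- (seq_len(grid_shape[3]) - 1) * sp[2]
  dz2 <- ((z - center[1]) / semi[1])^2
  dr2 <- ((r - center[2]) / semi[2])^2
  dc2 <- ((cc - center[3]) / semi[3])^2
  outer(dz2, outer(dr2, dc2, `+`), `+`) <= 1
}

#' Generate a paired MR/CT thoracic phantom with known fat truth
#'
#' Deterministic given the spec's seed. Returns MR and CT grids (congruent,
#' emulating the anatomically matched multiplanar-reformatted pairs used
#' for threshold calibration), one rectangular intra-thoracic contour per
#' slice, muscle reference ROIs in the posterior band (outside the contour,
#' disjoint from fat), the ground-truth fat mask and its physical volume.
#'
#' @param spec a [thoracic_phantom_spec].
#' @return An object of class `phantom_bundle`: fields `mr`, `ct`,
#'   `thoracic_contours`, `muscle_rois`, `fat_truth`, `truth_volume_ml`.
#' @export
make_thoracic_phantom <- function(spec) {
  stopifnot(inherits(spec, "thoracic_phantom_spec"))
  .validate_fat_regions(spec)
  set.seed(spec$seed)
  d <- spec$grid_shape
  sp <- spec$pixel_spacing_mm
  slice_sp <- spec$slice_thickness_mm + spec$slice_gap_mm
  m <- spec$thoracic_contour_margin_px

  fat <- array(FALSE, d)
  rim <- array(FALSE, d)
  for (e in spec$fat_regions) {
    fat <- fat | .ellipsoid_mask(d, sp, slice_sp, e$center, e$semi_axes)
    if (spec$rim_thickness_px > 0) {
      grown <- e$semi_axes + spec$rim_thickness_px * c(0, sp)
      rim <- rim | .ellipsoid_mask(d, sp, slice_sp, e$center, grown)
    }
  }
  rim <- rim & !fat

  # posterior paravertebral muscle band: outside the contour on the
  # high-column side, spanning the central rows
  band_rows <- (m):(d[2] - m)
  band_cols <- (d[3] - m + 2):(d[3] - 2)
  muscle <- array(FALSE, d)
  muscle[, band_rows, band_cols] <- TRUE
  muscle <- muscle & !fat & !rim

  n <- prod(d)
  mr <- .rnorm_pos(n, spec$background_mean, spec$background_sd)
  dim(mr) <- d
  nm <- sum(muscle)
  mr[muscle] <- .rnorm_pos(nm, spec$muscle_mean, spec$muscle_sd)
  nf <- sum(fat)
  mr[fat] <- if (!is.null(spec$fat_signal_range))
    stats::runif(nf, spec$fat_signal_range[1], spec$fat_signal_range[2])
  else .rnorm_pos(nf, spec$fat_mean, spec$fat_sd)
  if (any(rim))
    mr[rim] <- stats::runif(sum(rim), spec$rim_signal_range[1],
                            spec$rim_signal_range[2])

  ct <- array(spec$ct_air_hu, d)
  ct[muscle | rim] <- stats::runif(sum(muscle | rim),
                                   spec$ct_muscle_hu_range[1],
                                   spec$ct_muscle_hu_range[2])
  ct[fat] <- stats::runif(nf, spec$ct_fat_hu_range[1], spec$ct_fat_hu_range[2])

  # one rectangular intra-thoracic contour per slice; pixel centers
  # m+1 .. n-m fall inside
  rect <- rbind(c(m + 0.5, m + 0.5), c(m + 0.5, d[3] - m + 0.5),
                c(d[2] - m + 0.5, d[3] - m + 0.5),
                c(d[2] - m + 0.5, m + 0.5))
  contours <- lapply(seq_len(d[1]), function(s) planar_contour(s, rect))

  roi_col <- d[3] - m + 2 + (length(band_cols) - 1) / 2
  rad_px <- ceiling(spec$roi_diameter_mm / 2 / min(sp)) + 1L
  roi_rows <- round(seq(band_rows[1] + rad_px,
                        band_rows[length(band_rows)] - rad_px,
                        length.out = spec$rois_per_slice))
  rois <- unlist(lapply(seq_len(d[1]), function(s)
    lapply(roi_rows, function(rr)
      circular_roi(s, c(rr, roi_col), spec$roi_diameter_mm))),
    recursive = FALSE)

  mr_grid <- voxel_grid(mr, sp, spec$slice_thickness_mm, spec$slice_gap_mm, "MR")
  ct_grid <- voxel_grid(ct, sp, spec$slice_thickness_mm, spec$slice_gap_mm, "CT")
  truth <- binary_mask(fat, provenance = "phantom fat truth")
  structure(
    list(mr = mr_grid, ct = ct_grid, thoracic_contours = contours,
         muscle_rois = rois, fat_truth = truth,
         muscle_truth = binary_mask(muscle, "phantom muscle band"),
         truth_volume_ml = sum(fat) * voxel_volume_mm3(mr_grid) / 1000,
         spec = spec),
    class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> %s, truth volume %.2f ml (%d fat voxels), %d contours, %d ROIs\n",
              paste(dim(x$mr$values), collapse = "x"), x$truth_volume_ml,
              sum(x$fat_truth$values), length(x$thoracic_contours),
              length(x$muscle_rois)))
  invisible(x)
}

#' Generate an LV short-axis LGE phantom with known scar
#'
#' Builds an annular myocardium between concentric endocardial and
#' epicardial contours on each slice and sets a contiguous angular sector
#' comprising `scar_fraction` of the myocardial voxels to hyperenhanced
#' intensities (emulating a subendocardial-based infarct extending through
#' the sector). The reference ROI is placed mid-wall in the middle of the
#' remote (non-scarred) arc. Remote and scar intensities are Gaussian with
#' common SD `remote_sd`; the precondition
#' `scar_mean > remote_mean + 5 * remote_sd` guarantees the truth is
#' recoverable by a 5-SD threshold.
#'
#' @param scar_fraction target fraction of myocardial voxels in \[0, 1\].
#' @param remote_mean,remote_sd remote myocardium signal distribution.
#' @param scar_mean scar signal mean.
#' @param seed RNG seed.
#' @param n_slices,n_inplane grid shape (slices, n_inplane, n_inplane).
#' @param pixel_spacing_mm,slice_thickness_mm,slice_gap_mm geometry, mm.
#' @param endo_radius_mm,epi_radius_mm annulus radii, mm.
#' @param n_vertices polygon resolution of the circular contours.
#' @param roi_diameter_mm reference-region diameter, mm.
#' @param scar_start_angle angular origin of the scar sector, radians.
#' @return List of class `lv_phantom`: `lge`, `endo`, `epi`,
#'   `reference_region`, `scar_truth`, `myo_truth`.
#' @export
make_lv_phantom <- function(scar_fraction, remote_mean = 100, remote_sd = 5,
                            scar_mean = 600, seed = 1L,
                            n_slices = 4, n_inplane = 192,
                            pixel_spacing_mm = c(1.5, 1.5),
                            slice_thickness_mm = 6, slice_gap_mm = 4,
                            endo_radius_mm = 27, epi_radius_mm = 45,
                            n_vertices = 72, roi_diameter_mm = 6,
                            scar_start_angle = 3 * pi / 4) {
  if (scar_fraction < 0 || scar_fraction > 1)
    stop("scar_fraction must be in [0, 1]")
  if (scar_mean <= remote_mean + 5 * remote_sd)
    stop("scar_mean must exceed remote_mean + 5 * remote_sd")
  if (epi_radius_mm <= endo_radius_mm) stop("degenerate annulus")
  set.seed(as.integer(seed))
  d <- c(n_slices, n_inplane, n_inplane)
  ctr <- (n_inplane + 1) / 2
  circle <- function(s, radius_px) {
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    planar_contour(s, cbind(ctr + radius_px * sin(th), ctr + radius_px * cos(th)))
  }
  r_endo_px <- endo_radius_mm / pixel_spacing_mm[1]
  r_epi_px <- epi_radius_mm / pixel_spacing_mm[1]
  endo <- lapply(seq_len(n_slices), circle, radius_px = r_endo_px)
  epi <- lapply(seq_len(n_slices), circle, radius_px = r_epi_px)

  myo <- array(FALSE, d)
  scar <- array(FALSE, d)
  for (s in seq_len(n_slices)) {
    ann <- rasterize_contour(epi[[s]], d)$values[s, , ] &
      !rasterize_contour(endo[[s]], d)$values[s, , ]
    myo[s, , ] <- ann
    if (scar_fraction > 0) {
      idx <- which(ann, arr.ind = TRUE)
      ang <- atan2(idx[, 1] - ctr, idx[, 2] - ctr) %% (2 * pi)
      rel <- (ang - scar_start_angle) %% (2 * pi)
      take <- round(scar_fraction * nrow(idx))
      if (take > 0) {
        sel <- order(rel)[seq_len(take)]
        sl <- array(FALSE, dim(ann))
        sl[idx[sel, , drop = FALSE]] <- TRUE
        scar[s, , ] <- sl
      }
    }
  }

  vals <- .rnorm_pos(prod(d), remote_mean, remote_sd)
  dim(vals) <- d
  if (any(scar)) vals[scar] <- .rnorm_pos(sum(scar), scar_mean, remote_sd)
  lge <- voxel_grid(vals, pixel_spacing_mm, slice_thickness_mm, slice_gap_mm, "MR")

  # reference ROI mid-wall, in the middle of the remote arc
  ref_ang <- (scar_start_angle + 2 * pi * scar_fraction +
              pi * (1 - scar_fraction)) %% (2 * pi)
  r_mid <- (r_endo_px + r_epi_px) / 2
  ref <- circular_roi(1L, c(ctr + r_mid * sin(ref_ang),
                            ctr + r_mid * cos(ref_ang)), roi_diameter_mm)
  structure(
    list(lge = lge, endo = endo, epi = epi, reference_region = ref,
         scar_truth = binary_mask(scar, "phantom scar truth"),
         myo_truth = binary_mask(myo, "phantom myocardium"),
         scar_fraction = scar_fraction),
    class = "lv_phantom")
}

#' @export
print.lv_phantom <- function(x, ...) {
  cat(sprintf("<lv_phantom> %s, %d myocardial voxels, scar fraction %.3f (target %.3f)\n",
              paste(dim(x$lge$values), collapse = "x"), sum(x$myo_truth$values),
              sum(x$scar_truth$values) / max(1, sum(x$myo_truth$values)),
              x$scar_fraction))
  invisible(x)
}

# ---- cohort simulation -----------------------------------------------------

.cohort_groups <- c("MetS-/MI-", "MetS+/MI-", "MetS-/MI+", "MetS+/MI+")

#' Specification of a four-group synthetic cohort
#'
#' Defaults reproduce the study cells of a MetS/MI cohort: group sizes
#' 16/32/30/32 and indexed-ITFV means/SDs 22.3±10.6, 28.6±12.6, 30.6±12.3,
#' 35.2±11.4 ml/kg/m². Scar burden in the MI+ groups follows a linear
#' coupling to indexed ITFV, `scar = intercept + scar_slope * indexed_itfv
#' + N(0, noise_sd_scar)`, truncated at 0 by resampling; the per-group
#' intercept defaults to `scar_mean - scar_slope * itfv_mean` so group scar
#' means land on their targets (21.1 and 21.0 % LV mass). A scalar
#' `scar_intercept` overrides this with a single common intercept. Waist
#' circumference is generated with correlation `waist_itfv_cor` to indexed
#' ITFV, providing a realistic collinearity structure for the regression
#' screen.
#'
#' @param n,itfv_mean,itfv_sd,bmi_mean,bmi_sd,scar_mean,age_mean,age_sd,female_prop,caucasian_prop,diabetes_prop,hypertension_prop,gfr_mean,gfr_sd,waist_mean,waist_sd
#'   length-4 vectors in group order MetS-/MI-, MetS+/MI-, MetS-/MI+,
#'   MetS+/MI+ (scar_mean is NA for the MI- groups).
#' @param scar_slope linear coupling of scar % to indexed ITFV.
#' @param scar_intercept NULL (per-group, derived from scar_mean) or scalar.
#' @param noise_sd_scar residual SD of scar %, % LV mass.
#' @param waist_itfv_cor correlation of waist with indexed ITFV.
#' @param seed RNG seed.
#' @export
cohort_spec <- function(n = c(16L, 32L, 30L, 32L),
                        itfv_mean = c(22.3, 28.6, 30.6, 35.2),
                        itfv_sd = c(10.6, 12.6, 12.3, 11.4),
                        bmi_mean = c(22.9, 32.5, 26.0, 30.4),
                        bmi_sd = c(2.3, 6.5, 4.2, 4.7),
                        scar_mean = c(NA, NA, 21.1, 21.0),
                        scar_slope = 0.8, scar_intercept = NULL,
                        noise_sd_scar = 11,
                        age_mean = c(42.3, 62.0, 60.1, 58.7),
                        age_sd = c(16.9, 10.2, 11.4, 14.8),
                        female_prop = c(0.44, 0.23, 0.14, 0.09),
                        caucasian_prop = c(0.62, 0.81, 0.79, 0.79),
                        diabetes_prop = c(0, 0.45, 0.07, 0.42),
                        hypertension_prop = c(0, 0.77, 0.45, 0.70),
                        gfr_mean = c(94, 81, 78, 76),
                        gfr_sd = c(18, 23, 20, 21),
                        waist_mean = c(88.7, 119.9, 106.4, 116.0),
                        waist_sd = c(25, 9, 14.3, 11),
                        waist_itfv_cor = 0.8,
                        seed = 1L) {
  lens <- vapply(list(n, itfv_mean, itfv_sd, bmi_mean, bmi_sd, scar_mean,
                      age_mean, age_sd, female_prop, caucasian_prop,
                      diabetes_prop, hypertension_prop, gfr_mean, gfr_sd,
                      waist_mean, waist_sd), length, 1L)
  if (any(lens != 4L)) stop("all group-wise fields must have length 4")
  if (any(n < 2)) stop("all group sizes must be >= 2")
  if (any(c(itfv_sd, bmi_sd, age_sd, gfr_sd, waist_sd, noise_sd_scar) < 0))
    stop("all SDs must be >= 0")
  if (any(is.na(scar_mean[3:4]))) stop("scar_mean required for the MI+ groups")
  if (abs(waist_itfv_cor) > 1) stop("waist_itfv_cor must be in [-1, 1]")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate a four-group cohort table
#'
#' Per subject: group label, BMI, indexed ITFV (ml/kg/m², truncated-normal
#' by resampling), absolute ITFV = indexed ITFV × BMI, scar % for MI+
#' subjects from the linear coupling in [cohort_spec()] (NA for MI-), and
#' covariates (age, sex, race, diabetes, GFR, waist, hypertension).
#' Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec].
#' @return A `data.frame`, one row per subject, `group` a factor with the
#'   four study cells in order.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  intercepts <- if (is.null(spec$scar_intercept))
    spec$scar_mean - spec$scar_slope * spec$itfv_mean
  else rep(spec$scar_intercept, 4)
  rows <- lapply(1:4, function(g) {
    ng <- spec$n[g]
    idx <- .rnorm_pos(ng, spec$itfv_mean[g], spec$itfv_sd[g])
    bmi <- .rnorm_pos(ng, spec$bmi_mean[g], spec$bmi_sd[g])
    mi <- g >= 3
    scar <- if (mi) {
      mu <- intercepts[g] + spec$scar_slope * idx
      .rnorm_pos(ng, mu, spec$noise_sd_scar)
    } else rep(NA_real_, ng)
    z_idx <- if (spec$itfv_sd[g] > 0) (idx - spec$itfv_mean[g]) / spec$itfv_sd[g] else rep(0, ng)
    waist <- spec$waist_mean[g] + spec$waist_sd[g] *
      (spec$waist_itfv_cor * z_idx +
       sqrt(1 - spec$waist_itfv_cor^2) * stats::rnorm(ng))
    data.frame(
      group = .cohort_groups[g],
      bmi = bmi,
      itfv_ml = idx * bmi,
      indexed_itfv = idx,
      scar_pct = scar,
      age = .rnorm_pos(ng, spec$age_mean[g], spec$age_sd[g]),
      sex = ifelse(stats::runif(ng) < spec$female_prop[g], "female", "male"),
      race = ifelse(stats::runif(ng) < spec$caucasian_prop[g], "caucasian", "other"),
      diabetes = stats::runif(ng) < spec$diabetes_prop[g],
      gfr = .rnorm_pos(ng, spec$gfr_mean[g], spec$gfr_sd[g]),
      waist_cm = waist,
      hypertension = stats::runif(ng) < spec$hypertension_prop[g],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$id <- sprintf("S%03d", seq_len(nrow(out)))
  out$group <- factor(out$group, levels = .cohort_groups)
  out[, c("id", setdiff(names(out), "id"))]
}
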