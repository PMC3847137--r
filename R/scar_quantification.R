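# STRM (signal threshold versus reference myocardium) scar quantification:
# annular myocardial mask from endo/epi contours, threshold >= 5 SD above a
# remote-myocardium reference region, scar reported as % of LV mass
# (voxel-count ratio; uniform tissue density cancels).

#' Myocardial geometry: endo/epi contour pairs plus reference region
#'
#' One endocardial and one epicardial contour per analysed slice, with the
#' endocardial contour strictly inside the epicardial one, and a circular
#' reference region traced in remote (normal) myocardium. The reference
#' region is supplied manually, mirroring clinical practice.
#'
#' @param endo,epi lists of [planar_contour], pairwise on the same slices.
#' @param reference_region a [circular_roi] in remote myocardium.
#' @return An object of class `myocardial_geometry`.
#' @export
myocardial_geometry <- function(endo, epi, reference_region) {
  if (length(endo) != length(epi) || length(endo) < 1L)
    stop("endo and epi must be non-empty lists of equal length")
  stopifnot(inherits(reference_region, "circular_roi"))
  se <- vapply(endo, function(x) x$slice_index, 1L)
  sp <- vapply(epi, function(x) x$slice_index, 1L)
  if (!identical(sort(se), sort(sp)) || anyDuplicated(se))
    stop("endo/epi contours must pair up one per slice")
  epi <- epi[match(se, sp)]
  for (i in seq_along(endo)) {
    inside <- .point_in_polygon(endo[[i]]$vertices[, 1],
                                endo[[i]]$vertices[, 2],
                                epi[[i]]$vertices)
    if (!all(inside)) stop("endocardial contour not inside epicardial contour")
    if (abs(.polygon_area(endo[[i]]$vertices)) >=
        abs(.polygon_area(epi[[i]]$vertices)))
      stop("endocardial area must be smaller than epicardial area")
  }
  structure(list(endo = endo, epi = epi, reference_region = reference_region),
            class = "myocardial_geometry")
}

#' Rasterized myocardial annulus
#'
#' Per slice, the epicardial region minus the endocardial region. Errors
#' if any analysed slice yields an empty annulus.
#'
#' @param geom a [myocardial_geometry].
#' @param grid_shape (slices, rows, cols).
#' @return A [binary_mask].
#' @export
myocardium_mask <- function(geom, grid_shape) {
  stopifnot(inherits(geom, "myocardial_geometry"))
  mask <- array(FALSE, grid_shape)
  for (i in seq_along(geom$endo)) {
    s <- geom$endo[[i]]$slice_index
    ann <- rasterize_contour(geom$epi[[i]], grid_shape)$values[s, , ] &
      !rasterize_contour(geom$endo[[i]], grid_shape)$values[s, , ]
    if (!any(ann)) stop("empty myocardial annulus on slice ", s)
    mask[s, , ] <- ann
  }
  binary_mask(mask, provenance = "myocardium epi minus endo")
}

#' STRM scar burden as % of LV mass
#'
#' Threshold = reference mean + k * SD (whole-stack reference region,
#' pooled pixels, n-1 SD); scar voxels are annulus voxels with value
#' `>= threshold`; the result is `100 * scar voxels / annulus voxels`.
#' Warns when the reference SD is exactly zero, in which case the
#' inclusive threshold degenerates to the reference mean and captures all
#' reference-valued myocardium.
#'
#' @param lge LGE [voxel_grid].
#' @param geom a [myocardial_geometry]; the reference region must lie
#'   entirely within the annulus.
#' @param k SD multiplier (default 5).
#' @return Scar percentage in \[0, 100\].
#' @export
scar_percent <- function(lge, geom, k = 5) {
  stopifnot(inherits(lge, "voxel_grid"))
  if (k <= 0) stop("'k' must be > 0")
  myo <- myocardium_mask(geom, dim(lge$values))
  ref_idx <- .roi_pixel_index(geom$reference_region, lge)
  if (!all(myo$values[ref_idx]))
    stop("reference region extends outside the myocardial annulus")
  stats <- reference_stats(lge, list(geom$reference_region))
  if (stats$sd == 0)
    warning("reference region has zero SD; threshold equals the reference mean")
  thr <- fat_threshold(stats, k)
  n_myo <- sum(myo$values)
  n_scar <- sum(lge$values[myo$values] >= thr)
  100 * n_scar / n_myo
}

#' Full STRM quantification report
#'
#' Like [scar_percent()] but returns the mask, threshold and counts.
#'
#' @inheritParams scar_percent
#' @return An object of class `scar_result`.
#' @export
quantify_scar <- function(lge, geom, k = 5) {
  myo <- myocardium_mask(geom, dim(lge$values))
  stats <- reference_stats(lge, list(geom$reference_region))
  thr <- fat_threshold(stats, k)
  scar <- myo$values & (lge$values >= thr)
  structure(
    list(scar_pct = 100 * sum(scar) / sum(myo$values),
         threshold = thr, k = k, reference = stats,
         n_scar = sum(scar), n_myocardium = sum(myo$values),
         scar_mask = binary_mask(scar, "STRM scar"),
         myocardium_mask = myo),
    class = "scar_result")
}

#' Read / write myocardial geometry (JSON interchange, 0-based coordinates)
#'
#' File layout: `{"endo": [contour...], "epi": [contour...],
#' "reference": roi}` with contours and ROIs encoded as in
#' [write_contours()] / [write_rois()].
#'
#' @param geom a [myocardial_geometry].
#' @param path JSON file path.
#' @rdname geometry_json
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "myocardial_geometry"))
  enc_ct <- function(ct) list(slice = ct$slice_index - 1L,
                              vertices = unname(ct$vertices - 1))
  r <- geom$reference_region
  jsonlite::write_json(
    list(endo = lapply(geom$endo, enc_ct),
         epi = lapply(geom$epi, enc_ct),
         reference = list(slice = r$slice_index - 1L, center = r$center - 1,
                          diameter_mm = r$diameter_mm)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname geometry_json
#' @export
read_geometry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec_ct <- function(ct) {
    v <- ct$vertices
    if (is.list(v)) v <- do.call(rbind, v)
    planar_contour(as.integer(ct$slice) + 1L, as.matrix(v) + 1)
  }
  as_list <- function(x) if (is.data.frame(x)) split(x, seq_len(nrow(x))) else x
  ref <- raw$reference
  myocardial_geometry(
    endo = lapply(as_list(raw$endo), dec_ct),
    epi = lapply(as_list(raw$epi), dec_ct),
    reference_region = circular_roi(as.integer(ref$slice) + 1L,
                                    unlist(ref$center) + 1, ref$diameter_mm))
}

#' @export
print.scar_result <- function(x, ...) {
  cat(sprintf("<scar_result> %.2f%% of LV mass (%d / %d voxels), threshold %.4g (k = %g)\n",
              x$scar_pct, x$n_scar, x$n_myocardium, x$threshold, x$k))
  invisible(x)
}
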