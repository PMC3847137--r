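# CT-anchored calibration of the MR threshold multiplier: Hounsfield-window
# fat segmentation on the co-registered CT, Dice agreement against the MR
# threshold segmentation over a grid of k, argmax selection. The Dice
# coefficient is the quantitative surrogate for the visual matching used
# when the multiplier was originally tuned.

#' Hounsfield-window fat segmentation on CT
#'
#' A voxel is fat iff its center lies inside the slice's contour and its
#' HU value lies within the window, both bounds inclusive (default
#' -190..-30 HU, the conventional adipose window).
#'
#' @param ct CT [voxel_grid].
#' @param contours list of [planar_contour].
#' @param window (low, high) HU.
#' @return A [binary_mask].
#' @export
segment_fat_ct <- function(ct, contours, window = c(-190, -30)) {
  stopifnot(inherits(ct, "voxel_grid"))
  if (ct$modality != "CT") stop("segment_fat_ct expects a CT grid")
  if (window[1] >= window[2]) stop("window low must be < high")
  d <- dim(ct$values)
  mask <- array(FALSE, d)
  for (ctur in contours) {
    region <- rasterize_contour(ctur, d)$values
    mask <- mask | (region & ct$values >= window[1] & ct$values <= window[2])
  }
  binary_mask(mask, provenance = sprintf("segment_fat_ct [%g, %g] HU",
                                         window[1], window[2]))
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`, defined as 1 when both masks are empty.
#'
#' @param a,b congruent [binary_mask]s (or logical arrays).
#' @return Score in \[0, 1\].
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "binary_mask")) a$values else a
  bv <- if (inherits(b, "binary_mask")) b$values else b
  if (!identical(dim(av), dim(bv))) stop("shape mismatch between masks")
  denom <- sum(av) + sum(bv)
  if (denom == 0) return(1)
  2 * sum(av & bv) / denom
}

#' Calibrate the SD multiplier against CT fat segmentation
#'
#' For each k in `k_grid`, segments fat on the MR at threshold
#' `reference mean + k * SD` and scores its per-slice Dice agreement with
#' the Hounsfield-window CT segmentation, averaged over the analysed
#' slices (those with a contour). The selected k is the argmax; ties go to
#' the smallest k (the more inclusive threshold is the conservative error
#' direction for fat volume). MR and CT must be congruent, as produced by
#' anatomically matched reformatting (no registration is performed here).
#'
#' @param mr,ct congruent MR and CT [voxel_grid]s.
#' @param contours list of [planar_contour] (shared by both modalities).
#' @param rois muscle reference ROIs on the MR.
#' @param k_grid SD multipliers to evaluate (default 4..16).
#' @param window CT fat window, HU.
#' @return An object of class `calibration_result`: `k_grid`,
#'   `mean_dice_per_k`, `selected_k`, `n_slices`.
#' @export
calibrate_k <- function(mr, ct, contours, rois, k_grid = 4:16,
                        window = c(-190, -30)) {
  stopifnot(inherits(mr, "voxel_grid"), inherits(ct, "voxel_grid"))
  if (length(k_grid) == 0) stop("empty k_grid")
  if (!identical(dim(mr$values), dim(ct$values)))
    stop("MR and CT volumes are not congruent")
  ord <- order(k_grid)
  k_grid <- k_grid[ord]
  slices <- sort(vapply(contours, function(x) x$slice_index, 1L))
  stats <- reference_stats(mr, rois)
  ct_mask <- segment_fat_ct(ct, contours, window)
  mean_dice <- vapply(k_grid, function(k) {
    mr_mask <- suppressWarnings(segment_fat(mr, contours, fat_threshold(stats, k)))
    per_slice <- vapply(slices, function(s)
      dice(mr_mask$values[s, , , drop = FALSE],
           ct_mask$values[s, , , drop = FALSE]), 1.0)
    mean(per_slice)
  }, 1.0)
  structure(
    list(k_grid = k_grid, mean_dice_per_k = mean_dice,
         selected_k = k_grid[which.max(mean_dice)],  # first max = smallest k
         n_slices = length(slices), reference = stats),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> selected k = %g over %d slices\n",
              x$selected_k, x$n_slices))
  tab <- data.frame(k = x$k_grid, mean_dice = round(x$mean_dice_per_k, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
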