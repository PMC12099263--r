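check_mask_pair <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks have mismatched grid shapes (", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"),
         "); resampling is deliberately not performed")
}

#' Dice similarity coefficient
#'
#' Overlap between two binary masks: `2|A n B| / (|A| + |B|)`, in `[0, 1]`
#' with 1 meaning identical masks. Symmetric in its arguments.
#'
#' If both masks are empty the overlap is undefined; `NA` is returned with
#' a warning, and such (case, label) cells are excluded from ranking means.
#'
#' @param a,b 3D logical arrays of identical shape.
#' @return A number in `[0, 1]`, or `NA` if both masks are empty.
#' @export
dice <- function(a, b) {
  check_mask_pair(a, b)
  na <- sum(a)
  nb <- sum(b)
  if (na == 0L && nb == 0L) {
    warning("both masks empty: Dice undefined")
    return(NA_real_)
  }
  2 * sum(a & b) / (na + nb)
}

#' Volumetric similarity
#'
#' Agreement between the two mask volumes irrespective of overlap:
#' `1 - | |A| - |B| | / (|A| + |B|)`. Equal volumes score 1 even with zero
#' overlap, so `volume_similarity(a, b) >= dice(a, b)` always holds.
#'
#' @inheritParams dice
#' @return A number in `[0, 1]`, or `NA` if both masks are empty.
#' @export
volume_similarity <- function(a, b) {
  check_mask_pair(a, b)
  na <- sum(a)
  nb <- sum(b)
  if (na == 0L && nb == 0L) {
    warning("both masks empty: volume similarity undefined")
    return(NA_real_)
  }
  1 - abs(na - nb) / (na + nb)
}

#' Border voxels of a binary mask
#'
#' A mask voxel is a border voxel if at least one of its six face
#' neighbours is outside the mask; the domain boundary counts as outside.
#'
#' @param mask 3D logical array.
#' @return 3D logical array marking border voxels.
#' @export
border_voxels <- function(mask) {
  d <- dim(mask)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  interior <-
    p[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    p[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    p[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    p[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    p[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    p[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  mask & !interior
}

#' Surface distance multisets between two masks
#'
#' Computes, for every border voxel of each mask, the Euclidean distance
#' in mm (honouring anisotropic voxel spacing) to the nearest border voxel
#' of the other mask. Distances are between border voxel centres; both
#' directed multisets are returned, ready for percentile summaries such as
#' [hd95()].
#'
#' Implemented via an exact Euclidean distance transform of each border
#' set, so the result equals the brute-force minimum over all border
#' pairs.
#'
#' @inheritParams dice
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return A list with numeric vectors `gt_to_pred` (distances from `a`'s
#'   border to `b`'s border) and `pred_to_gt` (the converse).
#' @export
surface_distances <- function(a, b, spacing = c(1, 1, 1)) {
  check_mask_pair(a, b)
  if (!any(a) || !any(b))
    stop("an empty mask has no surface; apply missing-label penalties instead")
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  d <- dim(a)
  ba <- border_voxels(a)
  bb <- border_voxels(b)
  dist_to_b <- cpp_edt3d(as.logical(bb), as.integer(d), spacing)
  dist_to_a <- cpp_edt3d(as.logical(ba), as.integer(d), spacing)
  list(
    gt_to_pred = dist_to_b[as.vector(ba)],
    pred_to_gt = dist_to_a[as.vector(bb)]
  )
}

#' 95th-percentile Hausdorff distance
#'
#' Robust variant of the Hausdorff distance between two mask surfaces: the
#' maximum over both directions of the 95th percentile of that direction's
#' border-to-border distance multiset, in mm. Percentiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7), so
#' scores are bit-reproducible; `percentile = 100` recovers the exact
#' symmetric Hausdorff distance.
#'
#' @inheritParams surface_distances
#' @param percentile Percentile in `(0, 100]`; default 95.
#' @return Distance in mm (non-negative).
#' @export
hd95 <- function(a, b, spacing = c(1, 1, 1), percentile = 95) {
  stopifnot(percentile > 0, percentile <= 100)
  sd <- surface_distances(a, b, spacing)
  max(
    quantile(sd$gt_to_pred, percentile / 100, type = 7, names = FALSE),
    quantile(sd$pred_to_gt, percentile / 100, type = 7, names = FALSE)
  )
}
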