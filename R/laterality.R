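# Interhemispheric laterality index of suprathreshold connectivity.

#' Laterality index of suprathreshold connectivity
#'
#' Counts suprathreshold (surviving) voxels inside the affected/dominant ROI
#' and inside the non-affected/non-dominant homotopic ROI and forms
#' `LI = (n_AD - n_NAND) / (n_AD + n_NAND)`, in \[-1, 1\]: +1 means all
#' suprathreshold connectivity sits in the affected/dominant ROI
#' (intra-hemispheric), -1 all in the opposite ROI (inter-hemispheric),
#' 0 symmetric.
#'
#' @param surviving A `binary_mask` of suprathreshold voxels (typically the
#'   GRF-surviving mask; a plain voxelwise-threshold mask is equally valid).
#' @param roi_ad ROI mask on the affected / dominant side.
#' @param roi_nand Homotopic ROI mask on the other side. Must be disjoint from
#'   `roi_ad`.
#' @param seed_id Optional provenance label.
#' @return A `laterality_result`: tibble row with `li`, `count_ad`,
#'   `count_nand` and `seed_id`.
#' @export
laterality_index <- function(surviving, roi_ad, roi_nand, seed_id = NA_character_) {
  stopifnot(inherits(surviving, "binary_mask"),
            inherits(roi_ad, "binary_mask"), inherits(roi_nand, "binary_mask"))
  assert_same_grid(surviving, roi_ad, "map and ROI")
  assert_same_grid(surviving, roi_nand, "map and ROI")
  if (any(unclass(roi_ad) == 1 & unclass(roi_nand) == 1)) {
    stop("ROIs must be disjoint (split shared voxels at the mid-sagittal plane first)",
         call. = FALSE)
  }
  s <- unclass(surviving) == 1
  n_ad <- sum(s & unclass(roi_ad) == 1)
  n_nand <- sum(s & unclass(roi_nand) == 1)
  if (n_ad + n_nand == 0) {
    stop("no suprathreshold connectivity in either ROI", call. = FALSE)
  }
  out <- tibble::tibble(li = (n_ad - n_nand) / (n_ad + n_nand),
                        count_ad = n_ad, count_nand = n_nand,
                        seed_id = seed_id)
  class(out) <- c("laterality_result", class(out))
  out
}

#' Split a mask into hemispheres at the mid-sagittal plane
#'
#' Assigns every voxel strictly to one hemisphere along the identified
#' left-right axis (for an even axis length the plane falls between the two
#' central slabs; for odd lengths the central slab is dropped), guaranteeing
#' the disjointness [laterality_index()] presumes.
#'
#' @param m A `binary_mask`.
#' @return A list with `left` and `right` `binary_mask`s.
#' @export
split_hemispheres <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  ax <- attr(m, "lr_axis")
  n <- dim(m)[ax]
  half <- floor(n / 2)
  keep_side <- function(lo, hi) {
    idx <- rep(list(quote(expr = )), 3)
    out <- array(0, dim(m))
    idx[[ax]] <- lo:hi
    sel <- do.call(`[`, c(list(unclass(m)), idx, list(drop = FALSE)))
    do.call(`[<-`, c(list(out), idx, list(sel)))
  }
  list(left = binary_mask(keep_side(1L, half), voxel_dims(m), ax),
       right = binary_mask(keep_side(n - half + 1L, n), voxel_dims(m), ax))
}
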