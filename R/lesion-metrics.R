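# Lesion-derived markers: weighted tract lesion load and lesion exclusion.

#' Weighted corticospinal-tract lesion load
#'
#' For every voxel where the lesion intersects the suprathreshold tract, the
#' voxel volume is weighted by one tenth of the voxel's tract probability on
#' the percent scale:
#' \deqn{wLL = \sum_{n=1}^{n_{max}} \tfrac{1}{10}\, I(n)\, V_{voxel}}
#' where `I(n)` is the tract probability of the n-th intersecting voxel in
#' percent and `V_voxel` the voxel volume in mm^3. A voxel at 10% probability
#' therefore contributes one voxel volume per 10 mm^3-analog, and a voxel at
#' 100% contributes ten times that. With `weighting = "squared"` the weight is
#' `(I(n)/10)^2 / 10` instead (probability applied twice).
#'
#' @param lesion A `binary_mask`.
#' @param tract A `prob_map` on the same grid (declared scale is respected).
#' @param tract_threshold Voxels with tract probability (fraction scale) at or
#'   below this value never count as intersecting (default 0: any positive
#'   probability intersects).
#' @param weighting `"linear"` (default) or `"squared"`.
#' @return A tibble with `wcst_ll` (weighted mm^3), `n_max` (intersecting
#'   voxel count), `overlap_mm3` (unweighted `n_max` x voxel volume),
#'   `voxel_volume_mm3` and the scale/weighting provenance.
#' @export
wcst_ll <- function(lesion, tract, tract_threshold = 0,
                    weighting = c("linear", "squared")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(lesion, "binary_mask"), inherits(tract, "prob_map"))
  assert_same_grid(lesion, tract, "lesion and tract")
  frac <- prob_fraction(tract)
  sel <- unclass(lesion) == 1 & frac > tract_threshold
  n_max <- sum(sel)
  vv <- voxel_volume(lesion)
  ipct <- frac[sel] * 100
  w <- if (weighting == "linear") ipct / 10 else (ipct / 10)^2 / 10
  tibble::tibble(wcst_ll = sum(w) * vv,
                 n_max = n_max,
                 overlap_mm3 = n_max * vv,
                 voxel_volume_mm3 = vv,
                 probability_scale = attr(tract, "scale"),
                 weighting = weighting)
}

#' Exclude lesioned voxels from analysis
#'
#' Lesioned voxels are removed from all subsequent statistics: for masks the
#' voxels are cleared; for a BOLD run or a connectivity Z map the voxels are
#' set to `NA` (and the map's analysis mask shrinks accordingly).
#'
#' @param x A `bold_run`, `binary_mask`, or `fc_map`.
#' @param lesion A `binary_mask` on the same grid.
#' @return Same class as `x`.
#' @export
apply_lesion_exclusion <- function(x, lesion) {
  stopifnot(inherits(lesion, "binary_mask"))
  if (sum(unclass(lesion)) == 0) return(x)
  if (inherits(x, "binary_mask")) {
    assert_same_grid(x, lesion, "mask and lesion")
    out <- unclass(x)
    out[unclass(lesion) == 1] <- 0
    return(binary_mask(out, voxel_dims(x), attr(x, "lr_axis")))
  }
  if (inherits(x, "bold_run")) {
    assert_same_grid(x, lesion, "run and lesion")
    d <- dim(x)
    arr <- unclass(x)
    les <- array(rep(unclass(lesion) == 1, d[4]), d)
    arr[les] <- NA_real_
    out <- structure(new_grid_attr(arr, voxel_dims(x), attr(x, "lr_axis")),
                     class = "bold_run")
    attr(out, "tr") <- attr(x, "tr")
    return(out)
  }
  if (inherits(x, "fc_map")) {
    assert_same_grid(x$mask, lesion, "map and lesion")
    x$z[unclass(lesion) == 1] <- NA_real_
    m <- unclass(x$mask)
    m[unclass(lesion) == 1] <- 0
    x$mask <- binary_mask(m, voxel_dims(x$mask), attr(x$mask, "lr_axis"))
    return(x)
  }
  stop("apply_lesion_exclusion: unsupported type", call. = FALSE)
}
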