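#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test lm pf pnorm pt qnorm quantile rnorm runif sd var
#' @importFrom utils head read.table write.table
NULL

# ---- image containers -------------------------------------------------------
#
# Lightweight S3 containers: a numeric array plus grid metadata. Masks and
# probability maps must live on exactly the grid of the image they refer to;
# mismatches are errors, never implicit resampling.

new_grid_attr <- function(x, voxel_dims, lr_axis) {
  stopifnot(is.numeric(voxel_dims), length(voxel_dims) == 3L)
  if (any(!is.finite(voxel_dims)) || any(voxel_dims <= 0)) {
    stop("voxel_dims must be positive and finite", call. = FALSE)
  }
  attr(x, "voxel_dims") <- as.numeric(voxel_dims)
  attr(x, "lr_axis") <- as.integer(lr_axis)
  x
}

#' Create a 3-D volume image
#'
#' The basic spatial container: a 3-D numeric grid with voxel dimensions in mm
#' and an identified left-right axis (used by [mirror_lr()] and the laterality
#' machinery).
#'
#' @param data 3-D numeric array; all values must be finite.
#' @param voxel_dims Numeric length-3, mm per axis; all positive.
#' @param lr_axis Which array axis runs left-right (1, 2 or 3).
#' @return A `volume_image` object.
#' @export
#' @examples
#' v <- volume_image(array(0, c(8, 8, 6)), voxel_dims = c(3, 3, 3))
#' voxel_volume(v)
volume_image <- function(data, voxel_dims = c(1, 1, 1), lr_axis = 1L) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("unsupported dimensionality: need a 3-D array", call. = FALSE)
  if (any(!is.finite(data))) stop("volume contains non-finite values", call. = FALSE)
  if (dim(data)[lr_axis] < 2L) stop("left-right axis must have length >= 2", call. = FALSE)
  structure(new_grid_attr(data, voxel_dims, lr_axis), class = "volume_image")
}

#' Create a 4-D BOLD run
#'
#' @param data 4-D numeric array, dimensions (x, y, z, t).
#' @param tr Repetition time in seconds (> 0).
#' @inheritParams volume_image
#' @return A `bold_run` object.
#' @export
bold_run <- function(data, tr, voxel_dims = c(1, 1, 1), lr_axis = 1L) {
  data <- as.array(data)
  if (length(dim(data)) != 4L) stop("unsupported dimensionality: need a 4-D array", call. = FALSE)
  if (any(!is.finite(data))) stop("BOLD run contains non-finite values", call. = FALSE)
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("tr must be a single positive number (seconds)", call. = FALSE)
  }
  out <- structure(new_grid_attr(data, voxel_dims, lr_axis), class = "bold_run")
  attr(out, "tr") <- as.numeric(tr)
  out
}

#' Create a binary mask on a reference grid
#'
#' @param data 3-D array of 0/1 (logical arrays are coerced).
#' @inheritParams volume_image
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, voxel_dims = c(1, 1, 1), lr_axis = 1L) {
  data <- as.array(data)
  if (is.logical(data)) data <- array(as.numeric(data), dim(data))
  if (length(dim(data)) != 3L) stop("unsupported dimensionality: need a 3-D array", call. = FALSE)
  if (!all(data %in% c(0, 1))) stop("mask values must be exactly 0 or 1", call. = FALSE)
  structure(new_grid_attr(data, voxel_dims, lr_axis), class = "binary_mask")
}

#' Create a probabilistic map
#'
#' Probabilistic ROI / tract / tissue volumes carry an explicit scale so that a
#' value of 80 on the percent scale and 0.8 on the fraction scale mean the same
#' thing everywhere downstream.
#'
#' @param data 3-D numeric array.
#' @param scale `"fraction"` (values in \[0, 1\]) or `"percent"` (\[0, 100\]).
#' @inheritParams volume_image
#' @return A `prob_map` object.
#' @export
prob_map <- function(data, scale = c("fraction", "percent"),
                     voxel_dims = c(1, 1, 1), lr_axis = 1L) {
  scale <- match.arg(scale)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("unsupported dimensionality: need a 3-D array", call. = FALSE)
  hi <- if (scale == "fraction") 1 else 100
  if (any(!is.finite(data)) || any(data < 0) || any(data > hi)) {
    stop(sprintf("probabilities outside the declared %s scale [0, %g]", scale, hi),
         call. = FALSE)
  }
  out <- structure(new_grid_attr(data, voxel_dims, lr_axis), class = "prob_map")
  attr(out, "scale") <- scale
  out
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s, voxels %s mm\n",
              paste(dim(x), collapse = "x"),
              paste(signif(voxel_dims(x), 3), collapse = "x")))
  invisible(x)
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<bold_run> %s, %d volumes, TR %.3g s, voxels %s mm\n",
              paste(d[1:3], collapse = "x"), d[4], attr(x, "tr"),
              paste(signif(voxel_dims(x), 3), collapse = "x")))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s, %d voxels set\n",
              paste(dim(x), collapse = "x"), sum(x == 1)))
  invisible(x)
}

#' @export
print.prob_map <- function(x, ...) {
  cat(sprintf("<prob_map> %s, scale %s, max %.3g\n",
              paste(dim(x), collapse = "x"), attr(x, "scale"), max(x)))
  invisible(x)
}

# ---- grid helpers -----------------------------------------------------------

#' Voxel dimensions and voxel volume
#'
#' @param x Any hemiconn image object.
#' @return `voxel_dims()`: mm per axis (length 3); `voxel_volume()`: mm^3.
#' @export
voxel_dims <- function(x) attr(x, "voxel_dims")

#' @rdname voxel_dims
#' @export
voxel_volume <- function(x) prod(attr(x, "voxel_dims"))

spatial_dim <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) d[1:3] else d
}

assert_same_grid <- function(a, b, what = "images") {
  if (!identical(spatial_dim(a), spatial_dim(b)) ||
      !isTRUE(all.equal(voxel_dims(a), voxel_dims(b)))) {
    stop(sprintf("grid mismatch: %s must share shape and voxel dimensions", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Probabilities on the fraction scale
#'
#' Returns the raw array of a [prob_map()] converted to the \[0, 1\] fraction
#' scale regardless of how it was declared.
#'
#' @param p A `prob_map`.
#' @return A plain 3-D array in \[0, 1\].
#' @export
prob_fraction <- function(p) {
  stopifnot(inherits(p, "prob_map"))
  if (attr(p, "scale") == "percent") unclass(p) / 100 else unclass(p)
}

# ---- geometric / mask primitives -------------------------------------------

#' Mirror a volume across the mid-sagittal plane
#'
#' Reflects the grid along its identified left-right axis, so that a lesion in
#' the left hemisphere appears in the right hemisphere. All other metadata is
#' unchanged. Applying it twice returns the original volume.
#'
#' @param v A `volume_image`, `binary_mask`, `prob_map` or `bold_run`.
#' @return The same class of object, reflected.
#' @export
mirror_lr <- function(v) {
  ax <- attr(v, "lr_axis")
  if (is.null(ax) || !ax %in% 1:3) stop("unidentifiable left-right axis", call. = FALSE)
  d <- dim(v)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[ax]] <- d[ax]:1
  out <- do.call(`[`, c(list(unclass(v)), idx, list(drop = FALSE)))
  attributes(out) <- attributes(v)
  out
}

#' Threshold a probabilistic map into a binary mask
#'
#' Inclusive thresholding: voxels with probability greater than *or equal to*
#' `thr` are kept (so an 80% tissue probability passes a 0.80 threshold).
#' Percent-scale maps are converted before comparison.
#'
#' @param p A `prob_map`.
#' @param thr Threshold as a fraction, strictly inside (0, 1).
#' @return A `binary_mask` on the same grid.
#' @export
threshold_binarize <- function(p, thr) {
  stopifnot(inherits(p, "prob_map"))
  if (!is.numeric(thr) || length(thr) != 1L || !is.finite(thr) || thr <= 0 || thr >= 1) {
    stop("thr must lie strictly inside (0, 1)", call. = FALSE)
  }
  frac <- prob_fraction(p)
  binary_mask(array(as.numeric(frac >= thr), dim(frac)),
              voxel_dims = voxel_dims(p), lr_axis = attr(p, "lr_axis"))
}

#' Voxel count and volume of a mask
#'
#' @param m A `binary_mask`.
#' @return A tibble with `voxel_count` and `volume_mm3`.
#' @export
mask_stats <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  n <- sum(unclass(m) == 1)
  tibble::tibble(voxel_count = n, volume_mm3 = n * voxel_volume(m))
}
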