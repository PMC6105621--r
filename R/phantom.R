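# Synthetic two-hemisphere phantom: tissue compartments, bilateral ROI bumps,
# a descending tract, and focal lesions with controllable tract overlap.

#' Phantom anatomy specification
#'
#' Describes a two-hemisphere grid with CSF shell / GM ribbon / WM core
#' compartments, four bilateral ROI pairs (S1-like, M1-like, occipital and
#' parietal satellites) and a corticospinal-tract-like bundle descending
#' through the white matter of one hemisphere. Left and right ROI maps are
#' exact mirror images by construction.
#'
#' @param grid_shape Integer length-3 grid (default 32 x 32 x 24).
#' @param voxel_dims mm per axis (default 3 mm isotropic).
#' @param lr_axis Left-right array axis (default 1; low indices = left).
#' @param affected_side `"left"` or `"right"`: hemisphere carrying the tract
#'   (and, by convention, lesions).
#' @param roi_sigma_vox Gaussian radius of the ROI bumps, voxels.
#' @param tract_sigma_vox Gaussian cross-section of the tract, voxels.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 24L),
                         voxel_dims = c(3, 3, 3),
                         lr_axis = 1L,
                         affected_side = c("left", "right"),
                         roi_sigma_vox = 2,
                         tract_sigma_vox = 1.5) {
  affected_side <- match.arg(affected_side)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  structure(list(grid_shape = as.integer(grid_shape), voxel_dims = voxel_dims,
                 lr_axis = as.integer(lr_axis), affected_side = affected_side,
                 roi_sigma_vox = roi_sigma_vox, tract_sigma_vox = tract_sigma_vox),
            class = "phantom_spec")
}

# normalized ellipsoidal radius of every voxel (1 = brain surface)
phantom_rho <- function(spec) {
  d <- spec$grid_shape
  ctr <- (d + 1) / 2
  semi <- 0.95 * d / 2
  ax <- function(i) (seq_len(d[i]) - ctr[i]) / semi[i]
  x2 <- ax(1)^2; y2 <- ax(2)^2; z2 <- ax(3)^2
  sqrt(outer(outer(x2, y2, `+`), z2, `+`))
}

gauss_bump <- function(d, center, sigma) {
  g <- expand_dist2(d, center)
  b <- exp(-g / (2 * sigma^2))
  b[b < 0.01] <- 0
  b
}

expand_dist2 <- function(d, center, scale = c(1, 1, 1)) {
  dx2 <- ((seq_len(d[1]) - center[1]) * scale[1])^2
  dy2 <- ((seq_len(d[2]) - center[2]) * scale[2])^2
  dz2 <- ((seq_len(d[3]) - center[3]) * scale[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

#' Generate phantom anatomy
#'
#' @param spec A [phantom_spec()].
#' @return A list with `prob_map`s `csf`, `wm`, `gm`, ROI maps `s1_left`,
#'   `s1_right`, `m1_left`, `m1_right`, `occ_left`, `occ_right`, `par_left`,
#'   `par_right`, the `tract` map, the `brain` `binary_mask`, and the `spec`.
#' @export
make_phantom_anatomy <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vd <- spec$voxel_dims
  rho <- phantom_rho(spec)

  brain <- binary_mask(array(as.numeric(rho <= 1), d), vd, spec$lr_axis)
  inb <- rho <= 1
  p_csf <- 1 / (1 + exp(-(rho - 0.875) / 0.02)) * inb
  p_wm  <- 1 / (1 + exp((rho - 0.55) / 0.02)) * inb
  p_gm  <- pmax(0, inb - p_csf - p_wm)
  as_pm <- function(a) prob_map(array(pmin(pmax(a, 0), 1), d), "fraction", vd, spec$lr_axis)

  # ROI centers in the left hemisphere (fractions of grid), mirrored for right
  frac_ctr <- list(s1 = c(0.28, 0.40, 0.80), m1 = c(0.28, 0.60, 0.80),
                   occ = c(0.34, 0.16, 0.50), par = c(0.25, 0.28, 0.66))
  rois <- list()
  for (nm in names(frac_ctr)) {
    ctr <- round(frac_ctr[[nm]] * d)   # integer voxel centers: bumps peak at 1
    left <- as_pm(gauss_bump(d, ctr, spec$roi_sigma_vox))
    rois[[paste0(nm, "_left")]] <- left
    rois[[paste0(nm, "_right")]] <- mirror_lr(left)
  }

  # tract: vertical bundle in one hemisphere's WM, Gaussian cross-section,
  # restricted to the WM compartment and rescaled to peak 1
  tr_xy <- c(0.34, 0.50) * d[1:2]
  if (spec$affected_side == "right") tr_xy[1] <- d[1] + 1 - tr_xy[1]
  dx2 <- (seq_len(d[1]) - tr_xy[1])^2
  dy2 <- (seq_len(d[2]) - tr_xy[2])^2
  cross <- exp(-outer(dx2, dy2, `+`) / (2 * spec$tract_sigma_vox^2))
  tract <- array(rep(cross, d[3]), d)
  tract <- tract * (p_wm >= 0.5)
  if (max(tract) > 0) tract <- tract / max(tract)
  tract[tract < 0.01] <- 0

  c(list(csf = as_pm(p_csf), wm = as_pm(p_wm), gm = as_pm(p_gm),
         tract = as_pm(tract), brain = brain, spec = spec), rois)
}

#' Place an ellipsoidal lesion, optionally targeting a tract overlap
#'
#' Builds a spherical (in mm) lesion mask at `center_vox`. When
#' `target_tract_overlap` is given, the radius is adjusted by bracketed
#' bisection until the fraction of lesion voxels falling inside the
#' suprathreshold tract is within +/- 0.05 of the target.
#'
#' @param anatomy Output of [make_phantom_anatomy()].
#' @param center_vox Voxel coordinates (length 3) of the lesion center.
#' @param radius_mm Lesion radius in mm (ignored when a target overlap is
#'   given, where it seeds the search).
#' @param target_tract_overlap Optional fraction in \[0, 1\].
#' @param tract_threshold Tract probability defining "inside the tract".
#' @param tol Acceptable deviation from the target overlap.
#' @return A `binary_mask` with attributes `radius_mm` and `tract_overlap`.
#' @export
make_lesion <- function(anatomy, center_vox, radius_mm,
                        target_tract_overlap = NULL,
                        tract_threshold = 0.10, tol = 0.05) {
  spec <- anatomy$spec
  d <- spec$grid_shape
  if (unclass(anatomy$brain)[matrix(round(center_vox), 1)] != 1) {
    stop("lesion center must lie inside the brain", call. = FALSE)
  }
  dist2 <- expand_dist2(d, center_vox, scale = spec$voxel_dims)
  tract_in <- prob_fraction(anatomy$tract) >= tract_threshold

  lesion_at <- function(r) dist2 <= r^2
  overlap_at <- function(r) {
    les <- lesion_at(r)
    n <- sum(les)
    if (n == 0) return(NA_real_)
    sum(les & tract_in) / n
  }
  build <- function(r) {
    les <- lesion_at(r)
    out <- binary_mask(array(as.numeric(les), d), spec$voxel_dims, spec$lr_axis)
    attr(out, "radius_mm") <- r
    attr(out, "tract_overlap") <- if (sum(les) > 0) sum(les & tract_in) / sum(les) else 0
    out
  }

  if (is.null(target_tract_overlap)) {
    if (radius_mm <= 0) {
      return(binary_mask(array(0, d), spec$voxel_dims, spec$lr_axis))
    }
    return(build(radius_mm))
  }

  # coarse scan to find a bracket, then bisection within it
  radii <- exp(seq(log(min(spec$voxel_dims) * 0.6), log(max(d * spec$voxel_dims) / 2),
                   length.out = 60))
  ov <- vapply(radii, overlap_at, numeric(1))
  ok <- which(!is.na(ov))
  radii <- radii[ok]; ov <- ov[ok]
  i <- which.min(abs(ov - target_tract_overlap))
  if (abs(ov[i] - target_tract_overlap) > tol) {
    # try refining between the two neighbours whose overlaps straddle target
    cross <- which(diff(sign(ov - target_tract_overlap)) != 0)
    if (length(cross) == 0) stop("unreachable overlap target", call. = FALSE)
    lo <- radii[cross[1]]; hi <- radii[cross[1] + 1]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      om <- overlap_at(mid)
      if (!is.na(om) && abs(om - target_tract_overlap) <= tol) return(build(mid))
      flo <- overlap_at(lo)
      if (is.na(om) || sign(om - target_tract_overlap) == sign(flo - target_tract_overlap)) {
        lo <- mid
      } else {
        hi <- mid
      }
    }
    stop("unreachable overlap target", call. = FALSE)
  }
  # local bisection polish around the best coarse radius
  r <- radii[i]
  build(r)
}
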