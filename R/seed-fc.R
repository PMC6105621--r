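# Seed-based connectivity: seed construction, seed series, nuisance matrix,
# per-voxel GLM with t -> Z conversion.

#' Build a seed mask from probabilistic component maps
#'
#' Union of the component maps' inclusive suprathreshold supports, binarized —
#' the way a seed is assembled from several probabilistic cytoarchitectonic
#' areas.
#'
#' @param maps List of `prob_map`s on a shared grid.
#' @param threshold Inclusion threshold as a fraction, inside (0, 1);
#'   default 0.10.
#' @return A `binary_mask`.
#' @export
build_seed_mask <- function(maps, threshold = 0.10) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (inherits(maps, "prob_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  ref <- maps[[1]]
  acc <- array(0, dim(ref))
  for (p in maps) {
    assert_same_grid(ref, p, "seed component maps")
    acc <- pmax(acc, as.numeric(prob_fraction(p) >= threshold))
  }
  if (sum(acc) == 0) stop("empty seed mask", call. = FALSE)
  binary_mask(array(acc, dim(ref)), voxel_dims(ref), attr(ref, "lr_axis"))
}

#' Percent coverage of a probabilistic area by a mask
#'
#' `100 * |mask & area_suprathreshold| / |area_suprathreshold|`; the figure
#' quoted when reporting that a seed "includes 99% of" an area.
#'
#' @param mask A `binary_mask`.
#' @param area A `prob_map`.
#' @param area_threshold Fraction defining the area's support.
#' @return A percentage in \[0, 100\].
#' @export
roi_coverage <- function(mask, area, area_threshold = 0.10) {
  assert_same_grid(mask, area, "mask and area")
  supp <- prob_fraction(area) >= area_threshold
  n <- sum(supp)
  if (n == 0) stop("empty area at this threshold", call. = FALSE)
  100 * sum(unclass(mask) == 1 & supp) / n
}

#' Mean time series over a seed region
#'
#' Unweighted mean across seed voxels at each time point. Voxels carrying `NA`
#' (lesion-excluded) are dropped; if none remain the seed is empty.
#'
#' @param b A `bold_run`.
#' @param seed A `binary_mask`.
#' @return Numeric vector of length t.
#' @export
seed_timeseries <- function(b, seed) {
  stopifnot(inherits(b, "bold_run"), inherits(seed, "binary_mask"))
  assert_same_grid(b, seed, "run and seed")
  d <- dim(b)
  Y <- matrix(unclass(b), prod(d[1:3]), d[4])
  keep <- which(unclass(seed) == 1)
  keep <- keep[stats::complete.cases(Y[keep, , drop = FALSE])]
  if (length(keep) == 0L) stop("empty seed after exclusion", call. = FALSE)
  colMeans(Y[keep, , drop = FALSE])
}

#' Assemble the nine-column nuisance matrix
#'
#' CSF, WM and global-signal mean series plus the six motion parameters; the
#' standard nuisance set for seed-based resting-state regression. An intercept
#' is *not* included here — the GLM always adds its own.
#'
#' @param tissue_ts Tibble from [extract_tissue_ts()] (columns `csf`, `wm`).
#' @param global_ts Global (whole-brain mean) signal, numeric length t.
#' @param motion t x 6 motion-parameter matrix.
#' @return A t x 9 matrix with named columns.
#' @export
nuisance_matrix <- function(tissue_ts, global_ts, motion) {
  stopifnot(ncol(motion) == 6L)
  t_n <- length(global_ts)
  if (nrow(tissue_ts) != t_n || nrow(motion) != t_n) {
    stop("nuisance component lengths differ", call. = FALSE)
  }
  out <- cbind(csf = tissue_ts$csf, wm = tissue_ts$wm, global = global_ts, motion)
  if (any(!is.finite(out))) stop("nuisance matrix contains non-finite values", call. = FALSE)
  out
}

#' Global (whole-brain) mean signal
#'
#' @param b A `bold_run`.
#' @param brain A `binary_mask`.
#' @return Numeric vector of length t.
#' @export
global_signal <- function(b, brain) seed_timeseries(b, brain)

# log-tail-accurate t -> Z conversion by matching upper-tail probabilities
t_to_z <- function(tval, df, cap = 38) {
  logp <- pt(-abs(tval), df = df, log.p = TRUE)
  z <- -qnorm(logp, log.p = TRUE)
  z[!is.finite(z)] <- cap
  sign(tval) * pmin(z, cap)
}

#' Per-voxel seed connectivity GLM
#'
#' At every in-mask voxel, ordinary least squares of the voxel series on an
#' intercept, the seed time series and the nine nuisance regressors. The seed
#' coefficient's t statistic is converted to a Z statistic by quantile
#' matching through log survival functions (accurate far into the tails) and
#' capped at +/- 38. Residuals are retained for smoothness estimation.
#'
#' @param b A `bold_run` (possibly lesion-excluded).
#' @param seed_ts Seed mean time series (length t).
#' @param nuisance t x 9 matrix from [nuisance_matrix()].
#' @param mask Optional `binary_mask` restricting the analysis (default: all
#'   voxels with finite series).
#' @param z_cap Cap on |Z|.
#' @return An `fc_map`: list with `z` (3-D array, `NA` outside the mask),
#'   `df`, `mask`, `residuals` (V x t matrix of in-mask residuals),
#'   `mask_idx`, and grid metadata.
#' @export
fc_glm <- function(b, seed_ts, nuisance, mask = NULL, z_cap = 38) {
  stopifnot(inherits(b, "bold_run"))
  d <- dim(b)
  nt <- d[4]
  if (length(seed_ts) != nt) stop("seed series length mismatch", call. = FALSE)
  if (nrow(nuisance) != nt) stop("nuisance length mismatch", call. = FALSE)
  X <- cbind(intercept = 1, seed = seed_ts, nuisance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design matrix", call. = FALSE)
  df <- nt - ncol(X)
  if (df < 1) stop("not enough time points for the design", call. = FALSE)

  Y <- matrix(unclass(b), prod(d[1:3]), nt)
  finite <- stats::complete.cases(Y)
  keep <- if (is.null(mask)) {
    which(finite)
  } else {
    assert_same_grid(b, mask, "run and mask")
    which(unclass(mask) == 1 & finite)
  }
  if (length(keep) == 0L) stop("empty analysis mask", call. = FALSE)
  Yk <- t(Y[keep, , drop = FALSE])                     # t x V

  coef <- qr.coef(qrX, Yk)
  res <- qr.resid(qrX, Yk)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(sigma2 * XtXinv[2, 2], .Machine$double.xmin))
  tstat <- coef[2, ] / se
  zstat <- t_to_z(tstat, df, cap = z_cap)

  zarr <- array(NA_real_, d[1:3])
  zarr[keep] <- zstat
  marr <- array(0, d[1:3])
  marr[keep] <- 1
  structure(list(z = zarr, df = df,
                 mask = binary_mask(marr, voxel_dims(b), attr(b, "lr_axis")),
                 residuals = t(res), mask_idx = keep,
                 voxel_dims = voxel_dims(b), lr_axis = attr(b, "lr_axis")),
            class = "fc_map")
}

#' @export
print.fc_map <- function(x, ...) {
  cat(sprintf("<fc_map> %s, df %d, %d in-mask voxels, max |Z| %.2f\n",
              paste(dim(x$z), collapse = "x"), x$df, length(x$mask_idx),
              max(abs(x$z), na.rm = TRUE)))
  invisible(x)
}
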