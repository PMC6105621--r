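# Signal-level preprocessing: volume discard, grand-mean scaling, spatial
# smoothing, temporal high-pass, tissue time-series extraction.

#' Discard initial volumes of a BOLD run
#'
#' Drops the first `k` volumes to allow steady-state magnetisation (default 5).
#'
#' @param b A `bold_run`.
#' @param k Number of leading volumes to drop; must be < number of volumes.
#' @return A shorter `bold_run`.
#' @export
discard_initial <- function(b, k = 5L) {
  stopifnot(inherits(b, "bold_run"))
  k <- as.integer(k)
  nt <- dim(b)[4]
  if (k < 0L) stop("k must be non-negative", call. = FALSE)
  if (k >= nt) stop(sprintf("cannot discard %d of %d volumes", k, nt), call. = FALSE)
  if (k == 0L) return(b)
  bold_run(unclass(b)[, , , (k + 1L):nt, drop = FALSE], tr = attr(b, "tr"),
           voxel_dims = voxel_dims(b), lr_axis = attr(b, "lr_axis"))
}

# 1-D Gaussian convolution matrix with mirror ("whole-sample" reflect)
# boundaries: symmetric, doubly stochastic, hence conserves both constants and
# the global sum.
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  C <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (o in -r:r) {
      i <- j + o
      # half-sample symmetric reflection: 0 -> 1, -1 -> 2, n+1 -> n ...
      # (gives a symmetric doubly-stochastic matrix: constants and the
      # global sum are both preserved exactly)
      while (i < 1L || i > n) {
        if (i < 1L) i <- 1L - i
        if (i > n) i <- 2L * n + 1L - i
      }
      C[i, j] <- C[i, j] + k[o + r + 1L]
    }
  }
  C
}

smooth_array3 <- function(arr, dims, sigma_vox) {
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  rest <- length(arr) / prod(dims)
  x <- array(arr, c(n1, n2, n3 * rest))
  if (sigma_vox[1] > 0) {
    x <- array(gauss_conv_matrix(n1, sigma_vox[1]) %*% matrix(x, n1), dim(x))
  }
  if (sigma_vox[2] > 0) {
    x <- aperm(x, c(2, 1, 3))
    x <- array(gauss_conv_matrix(n2, sigma_vox[2]) %*% matrix(x, n2), dim(x))
    x <- aperm(x, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    x <- array(x, c(n1, n2, n3, rest))
    x <- aperm(x, c(3, 1, 2, 4))
    x <- array(gauss_conv_matrix(n3, sigma_vox[3]) %*% matrix(x, n3), dim(x))
    x <- aperm(x, c(2, 3, 1, 4))
  }
  array(x, c(dims, rest))
}

#' Spatial Gaussian smoothing
#'
#' Separable 3-D Gaussian convolution applied per volume, with per-axis sigma
#' `fwhm / (2 sqrt(2 log 2)) / voxel_dim` so anisotropic voxels receive an
#' isotropic kernel in mm. Boundaries are handled by symmetric reflection,
#' which preserves constants and the global sum. `fwhm_mm = 0` is the
#' identity.
#'
#' @param b A `bold_run` or `volume_image`.
#' @param fwhm_mm Kernel full width at half maximum, mm (>= 0).
#' @return Same class as `b`.
#' @export
gaussian_smooth <- function(b, fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm < 0) {
    stop("fwhm_mm must be a single non-negative number", call. = FALSE)
  }
  if (fwhm_mm == 0) return(b)
  vd <- voxel_dims(b)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vd
  d <- dim(b)
  out <- smooth_array3(unclass(b), d[1:3], sigma_vox)
  if (inherits(b, "bold_run")) {
    bold_run(array(out, d), tr = attr(b, "tr"), voxel_dims = vd,
             lr_axis = attr(b, "lr_axis"))
  } else {
    volume_image(array(out, d), voxel_dims = vd, lr_axis = attr(b, "lr_axis"))
  }
}

# Hat matrix of the Gaussian-weighted running-line fit: row t0 holds the
# weights that produce the local linear fit evaluated at t0.
running_line_hat <- function(nt, sigma_vol) {
  tt <- seq_len(nt)
  H <- matrix(0, nt, nt)
  for (t0 in tt) {
    w <- exp(-(tt - t0)^2 / (2 * sigma_vol^2))
    sw <- sum(w)
    tw <- sum(w * tt) / sw
    dt <- tt - tw
    s2 <- sum(w * dt^2)
    H[t0, ] <- w / sw + (t0 - tw) * (w * dt) / s2
  }
  H
}

#' Temporal high-pass by Gaussian-weighted running-line detrend
#'
#' At each time point the value of a locally Gaussian-weighted least-squares
#' straight-line fit (weights `exp(-dt^2 / 2 sigma^2)`) is subtracted, and the
#' original temporal mean of each voxel is restored. A globally linear series
#' is annihilated exactly (up to its mean).
#'
#' @param b A `bold_run` with at least 3 time points.
#' @param sigma_s Gaussian width of the running fit, seconds (default 100).
#' @return A `bold_run` of the same length.
#' @export
highpass_gaussian_line <- function(b, sigma_s = 100) {
  stopifnot(inherits(b, "bold_run"))
  if (!is.numeric(sigma_s) || sigma_s <= 0) stop("sigma_s must be > 0", call. = FALSE)
  d <- dim(b)
  nt <- d[4]
  if (nt < 3L) stop("need at least 3 time points", call. = FALSE)
  sigma_vol <- sigma_s / attr(b, "tr")
  H <- running_line_hat(nt, sigma_vol)
  Y <- t(matrix(unclass(b), prod(d[1:3]), nt))      # t x V
  res <- Y - H %*% Y
  res <- sweep(res, 2, colMeans(Y) - colMeans(res), `+`)
  bold_run(array(t(res), d), tr = attr(b, "tr"), voxel_dims = voxel_dims(b),
           lr_axis = attr(b, "lr_axis"))
}

#' Grand-mean intensity normalisation
#'
#' Scales the whole 4-D run so its mean over all in-mask voxels and volumes is
#' 10000 (a fixed convention; any constant cancels in correlation-based
#' outputs).
#'
#' @param b A `bold_run`.
#' @param mask Optional `binary_mask` restricting the mean; default whole grid.
#' @param target Target grand mean.
#' @return A rescaled `bold_run`.
#' @export
grand_mean_normalize <- function(b, mask = NULL, target = 10000) {
  stopifnot(inherits(b, "bold_run"))
  d <- dim(b)
  arr <- unclass(b)
  if (is.null(mask)) {
    m <- mean(arr)
  } else {
    assert_same_grid(b, mask, "run and mask")
    keep <- which(unclass(mask) == 1)
    if (length(keep) == 0L) stop("empty mask", call. = FALSE)
    m <- mean(matrix(arr, prod(d[1:3]), d[4])[keep, ])
  }
  if (!is.finite(m) || m == 0) stop("zero mean: cannot normalize", call. = FALSE)
  bold_run(arr * (target / m), tr = attr(b, "tr"), voxel_dims = voxel_dims(b),
           lr_axis = attr(b, "lr_axis"))
}

#' Extract CSF / WM / GM mean time series
#'
#' Each tissue's series is the unweighted mean over voxels whose tissue
#' probability is at least `thr` (default 0.80).
#'
#' @param b A `bold_run`.
#' @param csf,wm,gm Tissue `prob_map`s on the run's grid.
#' @param thr Tissue probability threshold (fraction scale).
#' @return A tibble with columns `volume`, `csf`, `wm`, `gm`.
#' @export
extract_tissue_ts <- function(b, csf, wm, gm, thr = 0.80) {
  stopifnot(inherits(b, "bold_run"))
  d <- dim(b)
  Y <- matrix(unclass(b), prod(d[1:3]), d[4])
  one <- function(p, name) {
    assert_same_grid(b, p, sprintf("run and %s map", name))
    keep <- which(prob_fraction(p) >= thr)
    if (length(keep) == 0L) {
      stop(sprintf("empty tissue mask: no %s voxels reach probability %.2f", name, thr),
           call. = FALSE)
    }
    colMeans(Y[keep, , drop = FALSE])
  }
  tibble::tibble(volume = seq_len(d[4]),
                 csf = one(csf, "CSF"), wm = one(wm, "WM"), gm = one(gm, "GM"))
}
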