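# BOLD phantom: a shared-latent-factor generative model with closed-form
# planted correlations, plus drift, global signal, motion leak and white noise.

#' Connectivity coupling specification for the BOLD phantom
#'
#' Each homotopic ROI pair shares a latent signal; the inter-hemispheric
#' coupling `inter` is exactly the planted correlation between the two sides'
#' noiseless regional signals (`x_side = sqrt(c) z + sqrt(1 - c) u_side`).
#' A per-hemisphere factor (`intra`) couples regions within a hemisphere and a
#' global factor (`global_amp`) couples everything; both default small.
#'
#' @param inter Named numeric of per-pair inter-hemispheric couplings in
#'   \[0, 1\] (names among `s1`, `m1`, `occ`, `par`), or a single value applied
#'   to all pairs.
#' @param intra Within-hemisphere shared-factor loading.
#' @param global_amp Global-factor loading.
#' @param amp Signal amplitude at an ROI peak, in raw image units.
#' @param noise_sd White-noise standard deviation per voxel (> 0).
#' @param drift_amp,drift_period_s Slow sinusoidal drift amplitude and period.
#' @param motion_leak Linear admixture strength of the 6 motion columns.
#' @param seed RNG seed; simulation is a pure function of (spec, seed).
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(inter = 0.8, intra = 0.3, global_amp = 0.2,
                          amp = 5, noise_sd = 2,
                          drift_amp = 3, drift_period_s = 120,
                          motion_leak = 0, seed = 1L) {
  pairs <- c("s1", "m1", "occ", "par")
  if (length(inter) == 1L && is.null(names(inter))) {
    inter <- stats::setNames(rep(inter, 4L), pairs)
  } else {
    full <- stats::setNames(rep(0.5, 4L), pairs)
    full[names(inter)] <- inter
    inter <- full
  }
  if (any(inter < 0 | inter > 1)) stop("inter couplings must lie in [0, 1]", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(list(inter = inter, intra = intra, global_amp = global_amp,
                 amp = amp, noise_sd = noise_sd, drift_amp = drift_amp,
                 drift_period_s = drift_period_s, motion_leak = motion_leak,
                 seed = as.integer(seed)),
            class = "coupling_spec")
}

#' Simulate a BOLD run on the phantom
#'
#' Every GM voxel receives a weighted sum of regional signals (weights taper
#' with the ROI probability maps), CSF and WM voxels receive their own
#' compartment signals, and all brain voxels receive drift, global signal, an
#' optional motion leak and white noise on top of a constant baseline.
#'
#' @param anatomy Output of [make_phantom_anatomy()].
#' @param coupling A [coupling_spec()].
#' @param t Number of volumes (>= 30).
#' @param tr Repetition time, seconds.
#' @param baseline Constant added to all brain voxels.
#' @return A list with `bold` (a [bold_run()]) and `motion` (t x 6 matrix).
#' @export
simulate_bold <- function(anatomy, coupling = coupling_spec(), t = 150, tr = 2.3,
                          baseline = 1000) {
  stopifnot(inherits(coupling, "coupling_spec"))
  if (t < 30) stop("need at least 30 volumes", call. = FALSE)
  spec <- anatomy$spec
  d <- spec$grid_shape
  nvox <- prod(d)
  pairs <- c("s1", "m1", "occ", "par")

  withr::with_seed(coupling$seed, {
    lat_shared <- matrix(rnorm(t * 4), t, 4, dimnames = list(NULL, pairs))
    lat_side <- array(rnorm(t * 4 * 2), c(t, 4, 2))   # pair x side unique parts
    hemi <- matrix(rnorm(t * 2), t, 2)                # per-hemisphere factors
    glob <- rnorm(t)
    motion <- cbind(apply(matrix(rnorm(t * 3, 0, 0.02), t, 3), 2, cumsum),
                    apply(matrix(rnorm(t * 3, 0, 0.002), t, 3), 2, cumsum))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    leak_coef <- matrix(rnorm(nvox * 6), nvox, 6)
    phase <- runif(1, 0, 2 * pi)
    noise <- matrix(rnorm(nvox * t, 0, coupling$noise_sd), nvox, t)
    csf_sig <- rnorm(t)
    wm_sig <- rnorm(t)
  })

  # regional signals: x_{pair,side} then mixed with hemisphere + global factors
  a <- coupling$intra; g <- coupling$global_amp
  norm <- sqrt(1 + a^2 + g^2)
  region_sig <- function(pair, side_idx) {
    c_p <- coupling$inter[[pair]]
    x <- sqrt(c_p) * lat_shared[, pair] + sqrt(1 - c_p) * lat_side[, match(pair, pairs), side_idx]
    (x + a * hemi[, side_idx] + g * glob) / norm
  }

  Y <- matrix(0, nvox, t)
  for (pair in pairs) {
    for (side_idx in 1:2) {
      side <- c("left", "right")[side_idx]
      p <- as.numeric(prob_fraction(anatomy[[paste0(pair, "_", side)]]))
      nz <- which(p > 0)
      if (length(nz)) {
        Y[nz, ] <- Y[nz, ] + coupling$amp * p[nz] %o% region_sig(pair, side_idx)
      }
    }
  }
  csf_p <- as.numeric(prob_fraction(anatomy$csf))
  wm_p <- as.numeric(prob_fraction(anatomy$wm))
  Y <- Y + (coupling$amp * 0.8 * csf_p) %o% csf_sig
  Y <- Y + (coupling$amp * 0.4 * wm_p) %o% wm_sig

  brain <- as.numeric(unclass(anatomy$brain))
  tt <- seq_len(t) * tr
  drift <- coupling$drift_amp * sin(2 * pi * tt / coupling$drift_period_s + phase)
  Y <- Y + brain %o% drift + (g > 0) * (coupling$amp * 0.3 * brain) %o% glob
  if (coupling$motion_leak != 0) {
    mstd <- scale(motion)
    Y <- Y + coupling$motion_leak * brain * (leak_coef %*% t(mstd))
  }
  Y <- Y + noise
  Y <- Y + baseline * brain

  list(bold = bold_run(array(Y, c(d, t)), tr = tr, voxel_dims = spec$voxel_dims,
                       lr_axis = spec$lr_axis),
       motion = motion)
}
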