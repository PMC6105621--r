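# Monte-Carlo harnesses: GRF family-wise error calibration and the
# planted-asymmetry laterality experiment. Both are first-class study tools,
# shared by the test suite and the acceptance script.

# lag-1 autocorrelation of white noise convolved with a discrete Gaussian
# kernel, and the equivalent FWHM under the same difference-variance model the
# smoothness estimator uses.
discrete_kernel_fwhm <- function(fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  rho <- sum(k[-1] * k[-length(k)]) / sum(k^2)
  v <- 2 * (1 - rho)
  sqrt(4 * log(2) / v)
}

#' Family-wise error calibration of GRF cluster inference
#'
#' Simulates null smooth Gaussian Z fields (white noise convolved with a
#' Gaussian of known FWHM, standardised to unit variance), applies
#' [grf_cluster_threshold()] and reports the fraction of replicates with any
#' surviving cluster — the empirical family-wise error, which should sit near
#' the nominal `alpha`.
#'
#' @param n_rep Number of null replicates.
#' @param grid Cubic grid side length, voxels.
#' @param fwhm_vox Smoothing kernel FWHM in voxels.
#' @param z_thr Cluster-forming threshold.
#' @param alpha Nominal cluster-wise FWE level.
#' @param seed RNG seed.
#' @return A tibble with `fwe_rate`, `n_rep`, and the settings.
#' @export
grf_fwe_calibration <- function(n_rep = 500, grid = 32, fwhm_vox = 2,
                                z_thr = 2.3, alpha = 0.05, seed = 1L) {
  d <- rep(grid, 3L)
  mask <- binary_mask(array(1, d), voxel_dims = c(1, 1, 1))
  sm <- smoothness_known(discrete_kernel_fwhm(fwhm_vox), mask)
  sigma_vox <- rep(fwhm_vox / (2 * sqrt(2 * log(2))), 3L)
  hits <- withr::with_seed(seed, {
    vapply(seq_len(n_rep), function(i) {
      x <- smooth_array3(rnorm(prod(d)), d, sigma_vox)
      x <- (x - mean(x)) / sd(x)
      fc <- list(z = array(x, d), mask = mask, voxel_dims = c(1, 1, 1))
      thr <- grf_cluster_threshold(fc, sm, z_thr = z_thr, alpha = alpha)
      any(thr$clusters$surviving)
    }, logical(1))
  })
  tibble::tibble(fwe_rate = mean(hits), n_rep = n_rep, grid = grid,
                 fwhm_vox = fwhm_vox, z_thr = z_thr, alpha = alpha)
}

#' Laterality recovery under planted interhemispheric asymmetry
#'
#' Runs the full subject pipeline on BOLD phantoms whose S1 interhemispheric
#' coupling is varied while everything else is held fixed, and records the
#' recovered S1 laterality index. As the planted coupling decreases
#' (asymmetry increases) the LI should increase.
#'
#' @param couplings S1 inter-hemispheric coupling levels.
#' @param n_seeds Phantom replicates per level.
#' @param t Volumes per run.
#' @param config A [run_config()].
#' @param seed Base RNG seed.
#' @param anatomy Optional pre-built anatomy (defaults to [phantom_spec()]).
#' @return A tibble with `coupling`, `replicate`, `li_s1`, `li_m1`.
#' @export
phantom_li_experiment <- function(couplings = c(0.8, 0.5, 0.2, 0.0),
                                  n_seeds = 5, t = 150,
                                  config = run_config(), seed = 1L,
                                  anatomy = NULL) {
  if (is.null(anatomy)) anatomy <- make_phantom_anatomy(phantom_spec())
  grid <- tidyr::expand_grid(coupling = couplings, replicate = seq_len(n_seeds))
  purrr::pmap_dfr(grid, function(coupling, replicate) {
    cs <- coupling_spec(inter = c(s1 = coupling, m1 = 0.8, occ = 0.8, par = 0.8),
                        seed = seed + 1000L * match(coupling, couplings) + replicate)
    sim <- simulate_bold(anatomy, cs, t = t)
    res <- run_subject(sim$bold, sim$motion, anatomy, lesion = NULL,
                       config = config,
                       subject_id = sprintf("c%.1f_r%d", coupling, replicate))
    tibble::tibble(coupling = coupling, replicate = replicate,
                   li_s1 = res$markers$li_s1, li_m1 = res$markers$li_m1)
  })
}

#' Hierarchical-regression recovery experiment
#'
#' Simulates many cohorts from a known generative model and compares the
#' recovered R^2 change (block 2 = laterality index over block 1 = lesion
#' volume) against the analytic population value; with `b_li = 0` it instead
#' collects the F-change p-values, which should be uniform under the null.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param n Patients per cohort.
#' @param b_li Generative LI coefficient for NIHSS.
#' @param seed Base RNG seed.
#' @return A list with `delta_r2` (vector), `p_change` (vector) and
#'   `analytic` (population decomposition for the settings used).
#' @export
regression_recovery <- function(n_cohorts = 200, n = 100, b_li = 3.0, seed = 1L) {
  base <- cohort_spec(n_patients = n, n_controls = 0)
  base$betas$nihss[["b_li"]] <- b_li
  analytic <- cohort_population_r2(base, "nihss")
  dr2 <- pch <- numeric(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    sp <- base
    sp$seed <- as.integer(seed + i)
    tab <- simulate_cohort(sp)
    hr <- hierarchical_regression(tab, "nihss", "lesion_volume", "li_s1")
    dr2[i] <- hr$change$delta_r2
    pch[i] <- hr$change$p_change
  }
  list(delta_r2 = dr2, p_change = pch, analytic = analytic)
}
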