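# Per-subject and cohort orchestration.

#' Pipeline run configuration
#'
#' Collects every threshold of the subject-level pipeline in one place;
#' the defaults are the standard operating point (discard 5 volumes,
#' grand mean 10000, 6 mm FWHM smoothing, 100 s high-pass, 80% tissue
#' probability, 10% seed threshold, subject clusters Z > 2.3, group Z >= 3,
#' alpha 0.05).
#'
#' @param discard_k Leading volumes to discard.
#' @param grand_mean Grand-mean target.
#' @param fwhm_mm Spatial smoothing FWHM, mm.
#' @param hp_sigma_s High-pass running-line sigma, seconds.
#' @param tissue_thr Tissue probability threshold (fraction).
#' @param seed_thr Seed inclusion threshold (fraction).
#' @param z_thr Subject-level cluster-forming threshold (strict >).
#' @param group_z_thr Group-level threshold (inclusive >=).
#' @param alpha Cluster-wise FWE level.
#' @param li_input `"surviving"` (GRF-corrected mask) or `"voxelwise"`
#'   (plain Z > z_thr mask) as the laterality input.
#' @param wcst_weighting `"linear"` or `"squared"` (see [wcst_ll()]).
#' @param mirror Mirror all images across the mid-sagittal plane at ingest
#'   (used when a lesion sits on the non-configured side). Clinical scores are
#'   never flipped.
#' @return A `run_config` list.
#' @export
run_config <- function(discard_k = 5L, grand_mean = 10000, fwhm_mm = 6,
                       hp_sigma_s = 100, tissue_thr = 0.80, seed_thr = 0.10,
                       z_thr = 2.3, group_z_thr = 3.0, alpha = 0.05,
                       li_input = c("surviving", "voxelwise"),
                       wcst_weighting = c("linear", "squared"),
                       mirror = FALSE) {
  li_input <- match.arg(li_input)
  wcst_weighting <- match.arg(wcst_weighting)
  stopifnot(tissue_thr > 0, tissue_thr < 1, seed_thr > 0, seed_thr < 1,
            z_thr > 0, group_z_thr > 0, alpha > 0, alpha < 1, fwhm_mm >= 0,
            hp_sigma_s > 0)
  structure(list(discard_k = as.integer(discard_k), grand_mean = grand_mean,
                 fwhm_mm = fwhm_mm, hp_sigma_s = hp_sigma_s,
                 tissue_thr = tissue_thr, seed_thr = seed_thr, z_thr = z_thr,
                 group_z_thr = group_z_thr, alpha = alpha, li_input = li_input,
                 wcst_weighting = wcst_weighting, mirror = mirror),
            class = "run_config")
}

#' Run the full subject-level pipeline
#'
#' Ordered stages: optional mirroring, initial-volume discard, grand-mean
#' normalisation, spatial smoothing, temporal high-pass, nuisance assembly
#' (CSF / WM / global + 6 motion parameters), lesion exclusion, bilateral
#' S1 and M1 seed construction, per-seed connectivity GLM, residual
#' smoothness estimation, GRF cluster thresholding, laterality indices for
#' both seeds, and the weighted tract lesion load.
#'
#' @param bold A `bold_run` (full, pre-discard).
#' @param motion Motion matrix with one row per *original* volume (the first
#'   `discard_k` rows are dropped with the volumes).
#' @param anatomy Phantom-style anatomy list (tissue and ROI `prob_map`s,
#'   `tract`, `brain`, `spec`); for real data, an equivalently named list.
#' @param lesion Optional `binary_mask`.
#' @param config A [run_config()].
#' @param subject_id Provenance label.
#' @return A list with `markers` (one-row tibble), per-seed `fc` results
#'   (each with `z_map`, `clusters`, `surviving`, `smoothness`, `li`), the
#'   `wcst` tibble and the `config`.
#' @export
run_subject <- function(bold, motion, anatomy, lesion = NULL,
                        config = run_config(), subject_id = "subject") {
  stopifnot(inherits(config, "run_config"))
  spec <- anatomy$spec
  if (config$mirror) {
    bold <- mirror_lr(bold)
    if (!is.null(lesion)) lesion <- mirror_lr(lesion)
  }
  b <- discard_initial(bold, config$discard_k)
  motion <- motion[(config$discard_k + 1):nrow(motion), , drop = FALSE]
  b <- grand_mean_normalize(b, mask = anatomy$brain, target = config$grand_mean)
  b <- gaussian_smooth(b, config$fwhm_mm)
  b <- highpass_gaussian_line(b, config$hp_sigma_s)

  tissue <- extract_tissue_ts(b, anatomy$csf, anatomy$wm, anatomy$gm,
                              thr = config$tissue_thr)
  gs <- global_signal(b, anatomy$brain)
  nuis <- nuisance_matrix(tissue, gs, motion)

  analysis_mask <- anatomy$brain
  if (!is.null(lesion)) {
    b <- apply_lesion_exclusion(b, lesion)
    analysis_mask <- apply_lesion_exclusion(analysis_mask, lesion)
  }

  # four unilateral seed analyses: S1 and M1, affected and non-affected side;
  # the laterality index is read from the affected-seed map, counting
  # suprathreshold voxels in the affected vs the homotopic ROI
  affected <- spec$affected_side
  other <- setdiff(c("left", "right"), affected)
  seeds <- list()
  for (region in c("s1", "m1")) {
    for (side in c(affected, other)) {
      tag <- if (side == affected) "affected" else "nonaffected"
      seeds[[paste(region, tag, sep = "_")]] <- list(
        map = anatomy[[paste0(region, "_", side)]],
        ad = anatomy[[paste0(region, "_", affected)]],
        nand = anatomy[[paste0(region, "_", other)]],
        region = region, tag = tag)
    }
  }

  fc <- list()
  li_vals <- c(s1 = NA_real_, m1 = NA_real_)
  for (nm in names(seeds)) {
    sd_ <- seeds[[nm]]
    seed_mask <- build_seed_mask(list(sd_$map), threshold = config$seed_thr)
    if (!is.null(lesion)) seed_mask <- apply_lesion_exclusion(seed_mask, lesion)
    sts <- seed_timeseries(b, seed_mask)
    map <- fc_glm(b, sts, nuis, mask = analysis_mask)
    sm <- estimate_smoothness(map$residuals, map$mask)
    thr <- grf_cluster_threshold(map, sm, z_thr = config$z_thr,
                                 alpha = config$alpha)
    fc[[nm]] <- list(seed_mask = seed_mask, z_map = map, smoothness = sm,
                     clusters = thr$clusters, surviving = thr$surviving)
    if (sd_$tag == "affected") {
      li_mask <- if (config$li_input == "surviving") thr$surviving else {
        binary_mask(array(as.numeric(!is.na(map$z) & map$z > config$z_thr),
                          dim(map$z)), voxel_dims(map$mask), spec$lr_axis)
      }
      li <- tryCatch(
        laterality_index(li_mask,
                         threshold_binarize(sd_$ad, config$seed_thr),
                         threshold_binarize(sd_$nand, config$seed_thr),
                         seed_id = nm),
        error = function(e) tibble::tibble(li = NA_real_, count_ad = 0L,
                                           count_nand = 0L, seed_id = nm))
      li_vals[sd_$region] <- li$li
      fc[[nm]]$li <- li
    }
  }

  wcst <- if (is.null(lesion)) {
    tibble::tibble(wcst_ll = NA_real_, n_max = NA_integer_,
                   overlap_mm3 = NA_real_, voxel_volume_mm3 = voxel_volume(anatomy$brain),
                   probability_scale = attr(anatomy$tract, "scale"),
                   weighting = config$wcst_weighting)
  } else {
    wcst_ll(lesion, anatomy$tract, weighting = config$wcst_weighting)
  }
  lesion_vol <- if (is.null(lesion)) NA_real_ else mask_stats(lesion)$volume_mm3

  markers <- tibble::tibble(id = subject_id,
                            lesion_volume = lesion_vol,
                            wcst_ll = wcst$wcst_ll,
                            li_s1 = li_vals[["s1"]], li_m1 = li_vals[["m1"]])
  list(markers = markers, fc = fc, wcst = wcst, config = config,
       subject_id = subject_id)
}

#' Run a cohort: group maps and cohort statistics
#'
#' @param subjects Named list of [run_subject()] outputs.
#' @param scores Optional tibble with one row per subject (matched by `id`)
#'   carrying `nihss` and `chedoke_*` columns; merged into the marker table.
#' @param groups Character vector (`"patient"` / `"control"`) aligned with
#'   `subjects`; group maps are computed per group and seed.
#' @param config A [run_config()].
#' @return A list with `markers` (cohort tibble), `group_maps` (per group and
#'   seed), `correlations` and `regression` (when scores are available).
#' @export
run_cohort <- function(subjects, scores = NULL, groups = NULL,
                       config = run_config()) {
  stopifnot(length(subjects) >= 3L)
  markers <- dplyr::bind_rows(lapply(subjects, `[[`, "markers"))
  if (is.null(groups)) groups <- rep("patient", length(subjects))
  markers$group <- groups

  group_maps <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3L) next
    for (nm in names(subjects[[idx[1]]]$fc)) {
      maps <- lapply(subjects[idx], function(s) s$fc[[nm]]$z_map)
      group_maps[[paste(g, nm, sep = "_")]] <-
        group_glm(maps, group_z_thr = config$group_z_thr, alpha = config$alpha)
    }
  }

  out <- list(markers = markers, group_maps = group_maps, config = config)
  if (!is.null(scores)) {
    tab <- dplyr::left_join(markers, scores, by = "id")
    pat <- tab[tab$group == "patient", , drop = FALSE]
    outcomes <- intersect(c("nihss", "chedoke_arm", "chedoke_hand",
                            "chedoke_leg", "chedoke_foot"), names(pat))
    out$table <- tab
    out$correlations <- correlation_report(
      pat, markers = c("lesion_volume", "wcst_ll", "li_s1", "li_m1"),
      outcomes = outcomes)
    out$regression <- tryCatch(
      hierarchical_regression(pat, y = "nihss",
                              block1 = "lesion_volume", block2 = "li_s1"),
      error = function(e) NULL)
  }
  out
}
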