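# Group-level one-sample GLM across subject Z maps.

#' Group-level one-sample GLM
#'
#' Per voxel, an ordinary-least-squares one-sample model across subjects'
#' Z maps (t with n - 1 degrees of freedom, converted to Z), followed by GRF
#' cluster-extent thresholding at the group defaults (Z >= 3 inclusive,
#' alpha 0.05). Degenerate between-subject variance is handled by a variance
#' floor. This is an OLS group model, tagged as such in the provenance.
#'
#' @param z_maps List of >= 3 `fc_map`s on a common grid.
#' @param group_z_thr Group cluster-forming threshold (default 3.0, inclusive).
#' @param alpha Cluster-wise FWE level.
#' @param var_floor Lower bound on the between-subject variance.
#' @param sm Optional `smoothness_estimate`; by default estimated from the
#'   demeaned subject maps treated as residual volumes.
#' @return A list with `z_map` (group `fc_map`-like object), `clusters`,
#'   `surviving`, and `provenance`.
#' @export
group_glm <- function(z_maps, group_z_thr = 3.0, alpha = 0.05,
                      var_floor = 1e-8, sm = NULL) {
  n <- length(z_maps)
  if (n < 3L) stop("need at least 3 maps for a group model", call. = FALSE)
  d <- dim(z_maps[[1]]$z)
  for (m in z_maps) {
    if (!identical(dim(m$z), d)) stop("group maps must share one grid", call. = FALSE)
  }
  Z <- vapply(z_maps, function(m) as.numeric(m$z), numeric(prod(d)))  # V x n
  inmask <- rowSums(is.na(Z)) == 0
  if (!any(inmask)) stop("no common in-mask voxels", call. = FALSE)
  mu <- rowMeans(Z)
  v <- pmax(apply(Z, 1, var), var_floor)
  tstat <- mu / sqrt(v / n)
  zg <- array(NA_real_, d)
  zg[inmask] <- t_to_z(tstat[inmask], df = n - 1)
  vd <- z_maps[[1]]$voxel_dims
  marr <- array(0, d); marr[inmask] <- 1
  gmask <- binary_mask(marr, vd, z_maps[[1]]$lr_axis %||% 1L)
  gmap <- structure(list(z = zg, df = n - 1, mask = gmask,
                         voxel_dims = vd, lr_axis = z_maps[[1]]$lr_axis %||% 1L),
                    class = "fc_map")
  if (is.null(sm)) {
    res <- sweep(Z[inmask, , drop = FALSE], 1, mu[inmask])
    sm <- estimate_smoothness(res, gmask)
  }
  thr <- grf_cluster_threshold(gmap, sm, z_thr = group_z_thr, alpha = alpha,
                               inclusive = TRUE)
  list(z_map = gmap, clusters = thr$clusters, surviving = thr$surviving,
       smoothness = sm,
       provenance = list(model = "OLS one-sample (not Bayesian mixed-effects)",
                         df = n - 1, z_thr = group_z_thr, alpha = alpha))
}
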