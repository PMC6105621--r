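test_that("smoothness estimator behaves on white and smoothed noise", {
  d <- c(16, 16, 12)
  m <- binary_mask(array(1, d), c(1, 1, 1))
  # white noise: difference-variance estimator sits near sqrt(2 log 2) ~ 1.18
  fw <- vapply(1:20, function(i) {
    r <- withr::with_seed(300 + i, matrix(rnorm(prod(d) * 16), ncol = 16))
    mean(estimate_smoothness(r, m)$fwhm)
  }, numeric(1))
  expect_equal(mean(fw), sqrt(2 * log(2)), tolerance = 0.2 * sqrt(2 * log(2)))
  # noise smoothed at FWHM 2: estimate within 25% of the model-implied value
  # for a discrete kernel (simulation oracle)
  target <- hemiconn:::discrete_kernel_fwhm(2)
  fw2 <- vapply(1:20, function(i) {
    arr <- withr::with_seed(400 + i, array(rnorm(prod(d) * 10), c(d, 10)))
    smn <- array(apply(arr, 4, function(v)
      hemiconn:::smooth_array3(v, d, rep(2 / (2 * sqrt(2 * log(2))), 3))),
      c(d, 10))
    mean(estimate_smoothness(smn, m)$fwhm)
  }, numeric(1))
  expect_equal(mean(fw2), target, tolerance = 0.25 * target)
  # doubling the mask volume at equal smoothness doubles the RESELs
  s1 <- smoothness_known(2, binary_mask(array(1, c(10, 10, 10)), c(1, 1, 1)))
  s2 <- smoothness_known(2, binary_mask(array(1, c(20, 10, 10)), c(1, 1, 1)))
  expect_equal(s2$resels, 2 * s1$resels)
  expect_error(estimate_smoothness(matrix(0, prod(d), 5), m), "degenerate")
})

test_that("26-connectivity labelling agrees with an igraph oracle", {
  for (rep in 1:8) {
    d <- c(9, 8, 7)
    supra <- array(withr::with_seed(500 + rep, rbinom(prod(d), 1, 0.25)) == 1, d)
    lab <- hemiconn:::label_components_26(supra)
    memb <- igraph_components(supra)
    idx <- which(supra)
    expect_equal(max(lab), if (length(idx)) max(memb) else 0)
    if (length(idx)) {
      # same partition: labels must be a bijection of memberships
      expect_equal(length(unique(paste(lab[idx], memb))), max(memb))
    }
  }
})

test_that("cluster thresholding finds inserted clusters and orders the table", {
  d <- c(32, 32, 32)
  mask <- binary_mask(array(1, d), c(1, 1, 1))
  sm <- smoothness_known(2, mask)
  z0 <- array(0, d)
  fc0 <- list(z = z0, mask = mask, voxel_dims = c(1, 1, 1))
  expect_equal(nrow(grf_cluster_threshold(fc0, sm)$clusters), 0)

  # a ~500-voxel Z=6 sphere must be one surviving cluster with small p
  z <- array(0, d)
  ctr <- c(16, 16, 16)
  for (i in 1:32) for (j in 1:32) for (k in 1:32) {
    if (sum((c(i, j, k) - ctr)^2) <= 4.9^2) z[i, j, k] <- 6
  }
  expect_gt(sum(z > 0), 400)
  fc <- list(z = z, mask = mask, voxel_dims = c(1, 1, 1))
  thr <- grf_cluster_threshold(fc, sm, z_thr = 2.3, alpha = 0.05)
  expect_equal(nrow(thr$clusters), 1)
  expect_lt(thr$clusters$p_fwe, 0.05)
  expect_true(thr$clusters$surviving)
  expect_equal(sum(unclass(thr$surviving)), sum(z > 2.3))
  # the p must equal the direct evaluation of the implemented formula
  expect_equal(thr$clusters$p_fwe,
               grf_cluster_p(thr$clusters$extent, 2.3, sm), tolerance = 1e-12)
})

test_that("survivors are suprathreshold and monotone in alpha", {
  d <- c(24, 24, 24)
  mask <- binary_mask(array(1, d), c(1, 1, 1))
  sm <- smoothness_known(2, mask)
  x <- hemiconn:::smooth_array3(withr::with_seed(606, rnorm(prod(d))), d,
                                rep(2 / 2.3548, 3))
  x <- (x - mean(x)) / sd(x) * 1.8
  fc <- list(z = array(x, d), mask = mask, voxel_dims = c(1, 1, 1))
  t1 <- grf_cluster_threshold(fc, sm, z_thr = 2.3, alpha = 0.05)
  t2 <- grf_cluster_threshold(fc, sm, z_thr = 2.3, alpha = 0.20)
  expect_true(all(unclass(t1$surviving)[array(x, d) <= 2.3] == 0))
  surv1 <- t1$clusters$cluster_id[t1$clusters$surviving]
  surv2 <- t2$clusters$cluster_id[t2$clusters$surviving]
  expect_true(all(surv1 %in% surv2))
  # p-values live in [0, 1] and decrease with extent
  ks <- c(1, 5, 20, 80, 300)
  ps <- grf_cluster_p(ks, 2.3, sm)
  expect_true(all(ps >= 0 & ps <= 1))
  expect_true(all(diff(ps) <= 0))
})

test_that("cluster labelling reports overlap percentages and peak labels", {
  d <- c(12, 12, 8)
  mask <- binary_mask(array(1, d), c(1, 1, 1))
  z <- array(0, d)
  z[2:6, 2:6, 3:5] <- 5   # 75-voxel block straddling two labels
  fc <- list(z = z, mask = mask, voxel_dims = c(1, 1, 1))
  thr <- grf_cluster_threshold(fc, smoothness_known(2, mask), z_thr = 2.3)
  la <- array(0, d); la[2:4, 2:6, 3:5] <- 1    # 60% of the block
  lb <- array(0, d); lb[5:6, 2:6, 3:5] <- 1    # 40%
  lab <- label_clusters(thr, fc, list(a = binary_mask(la, c(1, 1, 1)),
                                      b = binary_mask(lb, c(1, 1, 1))))
  expect_equal(lab$pct_a, 60)
  expect_equal(lab$pct_b, 40)
  expect_equal(lab$peak_label, "a")
  empty <- grf_cluster_threshold(list(z = array(0, d), mask = mask,
                                      voxel_dims = c(1, 1, 1)),
                                 smoothness_known(2, mask))
  expect_equal(nrow(label_clusters(empty, fc, list(a = binary_mask(la, c(1, 1, 1))))), 0)
})

test_that("group GLM matches a per-voxel one-sample t oracle", {
  d <- c(10, 10, 6)
  vd <- c(3, 3, 3)
  mask <- binary_mask(array(1, d), vd)
  mk <- function(arr) structure(list(z = arr, df = 100, mask = mask,
                                     voxel_dims = vd, lr_axis = 1L),
                                class = "fc_map")
  base <- withr::with_seed(70, array(rnorm(prod(d), mean = 1), d))
  maps <- lapply(1:5, function(i) {
    mk(base + withr::with_seed(70 + i, array(rnorm(prod(d), sd = 0.5), d)))
  })
  g <- group_glm(maps, sm = smoothness_known(2, mask))
  Z <- sapply(maps, function(m) as.numeric(m$z))
  i <- 137
  t_or <- t.test(Z[i, ])$statistic
  z_or <- hemiconn:::t_to_z(t_or, df = 4)
  expect_equal(g$z_map$z[i], unname(z_or), tolerance = 1e-10)
  # identical maps: group Z sign matches input sign everywhere nonzero
  same <- lapply(1:5, function(i) mk(base))
  gs <- group_glm(same, sm = smoothness_known(2, mask))
  expect_true(all(sign(gs$z_map$z[base != 0]) == sign(base[base != 0])))
  expect_error(group_glm(maps[1:2]), "at least 3")
})
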