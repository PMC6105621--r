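test_that("seed masks are unions of suprathreshold supports", {
  d <- c(10, 10, 6)
  bump <- function(ctr) {
    g <- array(0, d)
    for (i in 1:10) for (j in 1:10) for (k in 1:6) {
      g[i, j, k] <- exp(-sum((c(i, j, k) - ctr)^2) / 4)
    }
    prob_map(g, "fraction", c(3, 3, 3))
  }
  p1 <- bump(c(3, 3, 3)); p2 <- bump(c(8, 8, 4))
  m <- build_seed_mask(list(p1, p2), 0.10)
  oracle <- (prob_fraction(p1) >= 0.10) | (prob_fraction(p2) >= 0.10)
  expect_equal(unclass(m), array(as.numeric(oracle), d), ignore_attr = TRUE)
  expect_error(build_seed_mask(list(p1), 1.0), "inside")
  expect_error(build_seed_mask(list(prob_map(array(0.05, d), voxel_dims = c(3, 3, 3))),
                               0.10), "empty seed")
})

test_that("roi_coverage counts overlap percentages", {
  d <- c(6, 6, 4)
  area <- prob_map(array(c(rep(0.5, 40), rep(0, prod(d) - 40)), d),
                   voxel_dims = c(3, 3, 3))
  full <- binary_mask(array(1, d), c(3, 3, 3))
  expect_equal(roi_coverage(full, area), 100)
  none <- binary_mask(array(0, d), c(3, 3, 3))
  expect_equal(roi_coverage(none, area), 0)
  half <- array(0, d); half[1:20] <- 1
  expect_equal(roi_coverage(binary_mask(half, c(3, 3, 3)), area), 50)
  expect_error(roi_coverage(full, prob_map(array(0, d), voxel_dims = c(3, 3, 3))),
               "empty area")
})

test_that("seed_timeseries is the unweighted voxel mean", {
  d <- c(4, 4, 3); nt <- 15
  arr <- array(withr::with_seed(21, rnorm(prod(d) * nt)), c(d, nt))
  b <- bold_run(arr, tr = 2, voxel_dims = c(3, 3, 3))
  one <- array(0, d); one[2, 2, 2] <- 1
  expect_equal(seed_timeseries(b, binary_mask(one, c(3, 3, 3))), arr[2, 2, 2, ])
  # cancellation of s and -s
  arr2 <- arr; arr2[1, 1, 1, ] <- 1:nt; arr2[2, 1, 1, ] <- -(1:nt)
  two <- array(0, d); two[1:2, 1, 1] <- 1
  expect_equal(seed_timeseries(bold_run(arr2, tr = 2, voxel_dims = c(3, 3, 3)),
                               binary_mask(two, c(3, 3, 3))), rep(0, nt))
  # random block equals a brute-force mean
  blk <- array(withr::with_seed(22, rbinom(prod(d), 1, 0.5)), d)
  sel <- which(blk == 1)
  brute <- colMeans(matrix(arr, prod(d), nt)[sel, ])
  expect_equal(seed_timeseries(b, binary_mask(blk, c(3, 3, 3))), brute)
})

test_that("fc_glm matches a single-voxel OLS oracle and absorbs nuisance", {
  d <- c(6, 6, 4); nt <- 200
  nuis <- nuisance9(nt, seed = 5)
  seed_ts <- withr::with_seed(6, rnorm(nt))
  noise <- withr::with_seed(7, array(rnorm(prod(d) * nt), c(d, nt)))
  arr <- noise
  arr[3, 3, 2, ] <- 0.5 * seed_ts + noise[3, 3, 2, ]
  arr[4, 4, 2, ] <- nuis[, "csf"]              # pure nuisance voxel
  b <- bold_run(arr, tr = 2, voxel_dims = c(3, 3, 3))
  fc <- fc_glm(b, seed_ts, nuis)
  expect_equal(fc$df, nt - 11)
  # independent oracle via lm() at the planted voxel
  f <- lm(arr[3, 3, 2, ] ~ seed_ts + nuis)
  t_or <- summary(f)$coefficients["seed_ts", "t value"]
  z_or <- qnorm(pt(t_or, nt - 11, lower.tail = FALSE, log.p = TRUE),
                lower.tail = FALSE, log.p = TRUE)
  expect_equal(fc$z[3, 3, 2], z_or, tolerance = 1e-6)
  # nuisance voxel: seed Z ~ 0
  expect_lt(abs(fc$z[4, 4, 2]), 0.5)
  # perfect fit is capped, not infinite
  arr2 <- noise * 1e-12
  arr2[2, 2, 2, ] <- seed_ts
  fcp <- fc_glm(bold_run(arr2, tr = 2, voxel_dims = c(3, 3, 3)), seed_ts, nuis)
  expect_equal(fcp$z[2, 2, 2], 38)
  expect_error(fc_glm(b, seed_ts[-1], nuis), "length")
  expect_error(fc_glm(b, seed_ts, cbind(nuis, nuis[, 1])), "rank")
})

test_that("seed Z maps are invariant to nuisance-space shifts of the data", {
  d <- c(8, 8, 6); nt <- 80
  nuis <- nuisance9(nt, seed = 9)
  seed_ts <- withr::with_seed(10, rnorm(nt))
  arr <- withr::with_seed(11, array(rnorm(prod(d) * nt), c(d, nt)))
  f1 <- fc_glm(bold_run(arr, tr = 2, voxel_dims = c(3, 3, 3)), seed_ts, nuis)
  for (rep in 1:3) {
    combo <- nuis %*% withr::with_seed(20 + rep, rnorm(9, sd = 5))
    arr2 <- arr + array(rep(combo, each = prod(d)), c(d, nt))
    f2 <- fc_glm(bold_run(arr2, tr = 2, voxel_dims = c(3, 3, 3)), seed_ts, nuis)
    expect_lt(max(abs(f1$z - f2$z), na.rm = TRUE), 1e-6)
  }
})

test_that("t -> Z conversion matches tail probabilities and keeps signs", {
  z <- hemiconn:::t_to_z(c(-2.5, 0, 2.5), df = 30)
  expect_equal(pnorm(z[3], lower.tail = FALSE), pt(2.5, 30, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(z[1], -z[3])
  expect_equal(z[2], 0)
  expect_equal(hemiconn:::t_to_z(Inf, df = 10), 38)   # capped
  expect_lt(hemiconn:::t_to_z(1e6, df = 10), 38)      # heavy t tail, finite Z
})
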