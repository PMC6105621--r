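test_that("discard_initial drops exactly k leading volumes", {
  b <- bold_run(array(rep(1:20, each = 8), c(2, 2, 2, 20)), tr = 2, voxel_dims = c(3, 3, 3))
  expect_equal(dim(discard_initial(b, 5))[4], 15)
  expect_equal(unclass(discard_initial(b, 5))[1, 1, 1, 1], 6)
  expect_identical(unclass(discard_initial(b, 0)), unclass(b))
  expect_error(discard_initial(b, 20), "discard")
})

test_that("gaussian_smooth matches a directly evaluated kernel on a delta", {
  d <- c(15, 15, 15)
  arr <- array(0, d); arr[8, 8, 8] <- 1
  v <- volume_image(arr, voxel_dims = c(3, 3, 3))
  out <- unclass(gaussian_smooth(v, 6))
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  r <- ceiling(4 * sigma)
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  # kernel oracle: separable product evaluated at offsets from the impulse
  # (impulse far from boundaries, so reflection plays no role)
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(1, 1, 1), c(0, 3, 2))) {
    expected <- prod(k1[off + r + 1])
    expect_equal(out[8 + off[1], 8 + off[2], 8 + off[3]], expected, tolerance = 1e-12)
  }
})

test_that("gaussian_smooth preserves constants and the global sum; fwhm 0 is identity", {
  v <- volume_image(array(withr::with_seed(7, runif(8 * 9 * 7)), c(8, 9, 7)),
                    voxel_dims = c(2, 3, 4))
  s <- gaussian_smooth(v, 6)
  expect_equal(sum(s), sum(v), tolerance = 1e-10)
  cv <- volume_image(array(5, c(8, 8, 6)), c(3, 3, 3))
  expect_equal(max(abs(unclass(gaussian_smooth(cv, 6)) - 5)), 0, tolerance = 1e-10)
  expect_identical(unclass(gaussian_smooth(v, 0)), unclass(v))
  expect_error(gaussian_smooth(v, -1), "non-negative")
})

test_that("highpass annihilates lines, passes fast sinusoids, keeps means", {
  nt <- 40
  d <- c(4, 4, 3)
  trend <- array(rep(seq_len(nt), each = prod(d)) * 0.7 + 2, c(d, nt))
  b <- bold_run(trend, tr = 2.5, voxel_dims = c(3, 3, 3))
  hp <- highpass_gaussian_line(b, 100)
  resid <- unclass(hp)[1, 1, 1, ] - mean(trend[1, 1, 1, ])
  trend_rms <- sqrt(mean((trend[1, 1, 1, ] - mean(trend[1, 1, 1, ]))^2))
  expect_lt(sqrt(mean(resid^2)), 1e-6 * trend_rms)
  # temporal mean preserved voxelwise
  expect_equal(apply(unclass(hp), 1:3, mean), apply(trend, 1:3, mean),
               tolerance = 1e-9)
  # fast sinusoid (period = 4 TR << sigma) passes nearly untouched; the oracle
  # is a direct per-timepoint weighted regression
  tr <- 2.5
  sine <- sin(2 * pi * seq_len(nt) / 4)
  sb <- bold_run(array(rep(sine, each = prod(d)), c(d, nt)), tr = tr,
                 voxel_dims = c(3, 3, 3))
  out <- unclass(highpass_gaussian_line(sb, 100))[1, 1, 1, ]
  oracle <- vapply(seq_len(nt), function(t0) {
    w <- exp(-((seq_len(nt) - t0) * tr)^2 / (2 * 100^2))
    f <- lm(sine ~ seq_len(nt), weights = w)
    sine[t0] - unname(predict(f))[t0]
  }, numeric(1))
  oracle <- oracle - mean(oracle) + mean(sine)   # mean restored as implemented
  expect_equal(out, oracle, tolerance = 1e-8)
  expect_gt(cor(out, sine), 0.99)
  # constant series unchanged
  cb <- bold_run(array(3, c(d, nt)), tr = 2, voxel_dims = c(3, 3, 3))
  expect_equal(max(abs(unclass(highpass_gaussian_line(cb, 100)) - 3)), 0,
               tolerance = 1e-10)
})

test_that("grand-mean normalisation scales to the target and is idempotent", {
  arr <- array(withr::with_seed(8, runif(4 * 4 * 3 * 10, 400, 600)), c(4, 4, 3, 10))
  b <- bold_run(arr, tr = 2, voxel_dims = c(3, 3, 3))
  n1 <- grand_mean_normalize(b)
  expect_equal(mean(unclass(n1)), 10000, tolerance = 1e-9)
  expect_equal(unclass(grand_mean_normalize(n1)), unclass(n1), tolerance = 1e-12)
  # two runs differing by a global factor become identical
  b2 <- bold_run(arr * 3.7, tr = 2, voxel_dims = c(3, 3, 3))
  expect_equal(unclass(grand_mean_normalize(b2)), unclass(n1), tolerance = 1e-9)
  expect_error(grand_mean_normalize(bold_run(array(0, c(4, 4, 3, 10)), tr = 2,
                                             voxel_dims = c(3, 3, 3))), "zero mean")
})

test_that("tissue series are means over suprathreshold voxels (voxel-loop oracle)", {
  d <- c(6, 6, 4); nt <- 12
  arr <- array(withr::with_seed(9, rnorm(prod(d) * nt)), c(d, nt))
  b <- bold_run(arr, tr = 2, voxel_dims = c(3, 3, 3))
  pcsf <- array(withr::with_seed(10, runif(prod(d))), d)
  pwm <- array(withr::with_seed(11, runif(prod(d))), d)
  pgm <- array(withr::with_seed(12, runif(prod(d))), d)
  ts <- extract_tissue_ts(b, prob_map(pcsf, voxel_dims = c(3, 3, 3)),
                          prob_map(pwm, voxel_dims = c(3, 3, 3)),
                          prob_map(pgm, voxel_dims = c(3, 3, 3)))
  oracle <- function(p) {
    sel <- which(p >= 0.8)
    out <- numeric(nt)
    for (t0 in seq_len(nt)) {
      acc <- 0
      for (v in sel) acc <- acc + matrix(arr, prod(d), nt)[v, t0]
      out[t0] <- acc / length(sel)
    }
    out
  }
  expect_equal(ts$csf, oracle(pcsf), tolerance = 1e-12)
  expect_equal(ts$gm, oracle(pgm), tolerance = 1e-12)
  low <- prob_map(array(0.79, d), voxel_dims = c(3, 3, 3))
  expect_error(extract_tissue_ts(b, low, low, low), "empty tissue mask")
})
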