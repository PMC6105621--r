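test_that("phantom anatomy is mirror-symmetric, deterministic, tract unilateral", {
  an <- default_anatomy()
  expect_identical(unclass(mirror_lr(an$s1_left)), unclass(an$s1_right))
  expect_identical(unclass(mirror_lr(an$m1_left)), unclass(an$m1_right))
  expect_equal(max(prob_fraction(an$s1_left)), 1)
  tract_mask <- threshold_binarize(an$tract, 0.10)
  xs <- which(unclass(tract_mask) == 1, arr.ind = TRUE)[, 1]
  expect_true(all(xs <= an$spec$grid_shape[1] / 2))  # left hemisphere only
  an2 <- make_phantom_anatomy(phantom_spec())
  expect_identical(unclass(an$gm), unclass(an2$gm))
  expect_identical(unclass(an$tract), unclass(an2$tract))
})

test_that("lesions hit their tract-overlap target (bisection + count oracle)", {
  an <- default_anatomy()
  ctr <- which(prob_fraction(an$tract) == max(prob_fraction(an$tract)),
               arr.ind = TRUE)[1, ]
  les <- make_lesion(an, ctr, radius_mm = 6, target_tract_overlap = 0.5)
  tract_in <- prob_fraction(an$tract) >= 0.10
  brute <- sum(unclass(les) == 1 & tract_in) / sum(unclass(les) == 1)
  expect_gte(brute, 0.45)
  expect_lte(brute, 0.55)
  expect_equal(attr(les, "tract_overlap"), brute)

  empty <- make_lesion(an, ctr, radius_mm = 0)
  expect_equal(sum(unclass(empty)), 0)

  far <- c(22, 16, 12)   # right hemisphere, far from the left-sided tract
  les0 <- make_lesion(an, far, radius_mm = 5)
  expect_equal(sum(unclass(les0) == 1 & tract_in), 0)
  expect_error(make_lesion(an, far, radius_mm = 5, target_tract_overlap = 0.9),
               "unreachable")
})

test_that("simulate_bold plants the specified interhemispheric correlation", {
  an <- default_anatomy()
  cs <- coupling_spec(inter = c(s1 = 0.8, m1 = 0.8, occ = 0.8, par = 0.8),
                      intra = 0, global_amp = 0, drift_amp = 0,
                      motion_leak = 0, amp = 5, noise_sd = 2, seed = 42)
  sim <- simulate_bold(an, cs, t = 200)
  b <- sim$bold
  roi_mean <- function(p) {
    keep <- which(prob_fraction(p) >= 0.5)
    colMeans(matrix(unclass(b), prod(dim(b)[1:3]), dim(b)[4])[keep, ])
  }
  mL <- roi_mean(an$s1_left); mR <- roi_mean(an$s1_right)
  # closed-form planted value for the shared-latent model:
  # r = c * a^2 pbar^2 / (a^2 pbar^2 + sigma^2 / n)
  pv <- prob_fraction(an$s1_left)
  keep <- which(pv >= 0.5)
  pbar <- mean(pv[keep]); nvox <- length(keep)
  planted <- 0.8 * 25 * pbar^2 / (25 * pbar^2 + 4 / nvox)
  expect_equal(cor(mL, mR), planted, tolerance = 0.1)
  # same seed twice -> bit-identical
  sim2 <- simulate_bold(an, cs, t = 200)
  expect_identical(unclass(sim$bold), unclass(sim2$bold))
  expect_identical(sim$motion, sim2$motion)
})

test_that("zero coupling gives near-zero interhemispheric ROI correlations", {
  an <- default_anatomy()
  cs0 <- coupling_spec(inter = 0, intra = 0, global_amp = 0, drift_amp = 0,
                       motion_leak = 0, amp = 5, noise_sd = 2, seed = 7)
  b <- simulate_bold(an, cs0, t = 200)$bold
  roi_mean <- function(p) {
    keep <- which(prob_fraction(p) >= 0.5)
    colMeans(matrix(unclass(b), prod(dim(b)[1:3]), dim(b)[4])[keep, ])
  }
  pairs <- list(c("s1_left", "s1_right"), c("m1_left", "m1_right"),
                c("occ_left", "occ_right"), c("par_left", "par_right"))
  rs <- vapply(pairs, function(p) cor(roi_mean(an[[p[1]]]), roi_mean(an[[p[2]]])),
               numeric(1))
  expect_lt(mean(abs(rs)), 0.15)
})

test_that("simulated cohorts obey the generative model", {
  # noiseless generative identity
  sp <- cohort_spec(n_patients = 10, n_controls = 0, seed = 3)
  for (nm in names(sp$betas)) sp$betas[[nm]]["sd"] <- 0
  tab <- simulate_cohort(sp)
  b <- sp$betas$nihss
  expect_equal(tab$nihss,
               pmax(0, b[["intercept"]] + b[["b_lesion"]] * tab$lesion_volume +
                      b[["b_li"]] * tab$li_s1), tolerance = 1e-12)
  # OLS recovers the planted coefficients within 3 SEs at n = 200
  sp2 <- cohort_spec(n_patients = 200, n_controls = 0, seed = 11)
  tab2 <- simulate_cohort(sp2)
  f <- lm(nihss ~ lesion_volume + li_s1, data = tab2)
  est <- summary(f)$coefficients
  expect_lt(abs(est["lesion_volume", 1] - sp2$betas$nihss[["b_lesion"]]),
            3 * est["lesion_volume", 2])
  expect_lt(abs(est["li_s1", 1] - sp2$betas$nihss[["b_li"]]),
            3 * est["li_s1", 2])
  # missing mask blanks exactly the requested cell
  sp3 <- cohort_spec(n_patients = 5, n_controls = 0, seed = 1,
                     missing = data.frame(row = 4, col = "chedoke_foot"))
  tab3 <- simulate_cohort(sp3)
  expect_true(is.na(tab3$chedoke_foot[4]))
  expect_equal(sum(is.na(tab3$chedoke_foot)), 1)
  expect_false(anyNA(tab3$chedoke_arm))
  # pure function of (spec, seed)
  expect_identical(simulate_cohort(sp3), simulate_cohort(sp3))
})
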