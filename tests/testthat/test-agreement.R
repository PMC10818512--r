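# Bland-Altman, repeatability coefficient, ICC(3,1), within-subject scope.

test_that("Bland-Altman on identical pairs is all-zero", {
  x <- c(1, 2, 3, 4)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
})

test_that("Bland-Altman matches hand arithmetic", {
  ba <- bland_altman(c(2, 3, 4), c(1, 1, 1))
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, 2 - 1.96)
  expect_equal(ba$loa_high, 2 + 1.96)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("limits of agreement reproduce the reference worked example", {
  loa <- limits_of_agreement(1.4, 2.3)
  expect_equal(round(loa[2], 1), 5.9)
  expect_equal(round(loa[1], 1), -3.1)
})

test_that("repeatability coefficient is 1.96 x RMS of differences", {
  expect_equal(repeatability_coefficient(c(0, 0, 0)), 0)
  expect_equal(repeatability_coefficient(c(2, 2, 2)), 1.96 * 2)
  expect_equal(repeatability_coefficient(c(-3, -3)), 1.96 * 3)
  # summary form reproduces the reference value 5.3 from mean 1.4, SD 2.3
  expect_equal(round(rc_from_summary(1.4, 2.3), 1), 5.3)
  expect_equal(rc_from_summary(1.4, 2.3), 1.96 * sqrt(1.4^2 + 2.3^2))
})

test_that("RC never decreases when a constant is added to all differences", {
  set.seed(5)
  d <- rnorm(200, 0, 2)
  rc0 <- repeatability_coefficient(d)
  for (c0 in c(0.5, 1, 2, 5))
    expect_gte(repeatability_coefficient(d + c0), rc0)
})

test_that("ICC(3,1) is exact on degenerate designs", {
  x <- c(1, 5, 9, 13, 2, 7)
  expect_equal(icc_3_1(x, x)$icc, 1)
  # consistency form ignores a constant inter-rater bias
  expect_equal(icc_3_1(x + 2.5, x)$icc, 1)
  expect_error(icc_3_1(rep(1, 5), rep(1, 5)), "undefined")
  expect_error(icc_3_1(1:2, 1:2), "at least 3")
})

# Independent oracle: two-way ANOVA mean squares via stats::aov
icc_oracle <- function(imu, omcs) {
  n <- length(imu)
  df <- data.frame(y = c(imu, omcs),
                   target = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ target + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; mse <- ms[3]
  (msr - mse) / (msr + mse)
}

test_that("ICC matches a brute-force ANOVA oracle on a toy table", {
  imu <- c(9, 10, 12, 14, 15, 17)
  omcs <- c(8, 11, 11, 15, 14, 18)
  expect_equal(icc_3_1(imu, omcs)$icc, icc_oracle(imu, omcs),
               tolerance = 1e-12)
})

test_that("ICC equals the ANOVA oracle on random small tables", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(5:20, 1)
    base <- rnorm(n, sd = runif(1, 0.5, 4))
    imu <- base + rnorm(n, sd = 0.5)
    omcs <- base + rnorm(n, sd = 0.5) + runif(1, -2, 2)
    expect_equal(icc_3_1(imu, omcs)$icc, icc_oracle(imu, omcs),
                 tolerance = 1e-10)
  }
})

test_that("ICC confidence interval brackets the estimate", {
  set.seed(8)
  base <- rnorm(50, sd = 3)
  r <- icc_3_1(base + rnorm(50, sd = 0.5), base + rnorm(50, sd = 0.5))
  expect_lte(r$ci_low, r$icc)
  expect_gte(r$ci_high, r$icc)
  expect_gt(r$icc, 0.9)
})

test_that("limits of agreement cover about 95% of Gaussian differences", {
  set.seed(10)
  n <- 10000
  omcs <- rnorm(n, 10, 3)
  imu <- omcs + rnorm(n, 1.4, 2.3)
  ba <- bland_altman(imu, omcs)
  cover <- mean(ba$differences >= ba$loa_low & ba$differences <= ba$loa_high)
  expect_gt(cover, 0.94)
  expect_lt(cover, 0.96)
})

test_that("within-subject analysis summarizes per-subject agreement", {
  subj <- rep(c("a", "b"), each = 4)
  omcs <- rep(5, 8)
  imu <- omcs + rep(c(1, 3), each = 4)     # constant differences 1 and 3
  ws <- within_subject_agreement(subj, imu, omcs)
  expect_equal(ws$per_subject$rc, c(1.96, 5.88))
  expect_equal(ws$rc_mean, 3.92)
  expect_equal(ws$rc_sd, stats::sd(c(1.96, 5.88)))
  expect_equal(ws$rc_sd, 2.771859, tolerance = 1e-6)
  # identical pairs everywhere: all zeros
  ws0 <- within_subject_agreement(subj, omcs + 0.0, omcs)
  expect_equal(ws0$rc_mean, 0)
  expect_equal(ws0$rc_sd, 0)
  expect_warning(
    within_subject_agreement(c("a", "a", "b", "c", "c"),
                             c(1, 2, 1, 1, 2), c(1, 1, 1, 1, 1)),
    "excluded")
})
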