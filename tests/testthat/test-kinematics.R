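# Segment angles, calibration, FSA, derivatives, stride length, stride table.

test_that("differentiate matches analytic derivatives", {
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  expect_equal(differentiate(3 * t + 1, fs), rep(3, length(t)),
               tolerance = 1e-9)
  f <- 2
  d <- differentiate(sin(2 * pi * f * t), fs)
  expect_equal(max(abs(d[10:190])), 2 * pi * f, tolerance = 0.01 * 2 * pi * f)
  d2 <- differentiate(4 * t^2, fs, order = 2L)
  expect_equal(d2[5:190], rep(8, 186), tolerance = 1e-6)
  expect_error(differentiate(c(1, 2), fs), "too short")
})

test_that("segment angles follow atan2 of vertical over walking direction", {
  mk <- function(dy, dz) list(
    toe = cbind(0, dy, dz), heel = cbind(0, 0, 0),
    knee = cbind(0, dy, dz), ankle = cbind(0, 0, 0))
  m <- mk(0.25, 0)
  expect_equal(as.numeric(foot_angle_omcs(m, cbind(1, 2))), 0)
  m10 <- mk(0.25, 0.25 * tan(10 * pi / 180))
  a10 <- strideval:::segment_angle(m10$toe, m10$heel)
  expect_equal(unname(a10[1]), 10, tolerance = 1e-9)
  # vertical shank reads 90 degrees; 45-degree shank reads 45
  sv <- shank_angle(mk(0, 0.4), "omcs")
  expect_equal(as.numeric(sv)[1], 90)
  s45 <- shank_angle(mk(0.3, 0.3), "omcs")
  expect_equal(as.numeric(s45)[1], 45)
  expect_error(strideval:::segment_angle(cbind(0, 0, 0), cbind(0, 0, 0)),
               "degenerate")
})

test_that("IMU foot calibration recovers the mounting tilt", {
  # constant pitch equal to the tilt during windows -> output 0 there
  imu <- list(euler_pitch = rep(25, 100))
  a <- foot_angle_imu(imu, cbind(10, 60))
  expect_equal(as.numeric(a)[10:59], rep(0, 50))
  expect_equal(attr(a, "calibration_offset"), 25)
  # full generator: recovered offset equals the profile's mounting tilt
  qe <- quiet_events_50()
  ffw <- foot_flat_windows(qe$events, "imu")
  ai <- foot_angle_imu(qe$trial$imu$foot_L, ffw$L)
  expect_equal(attr(ai, "calibration_offset"), 25, tolerance = 0.05)
  expect_error(foot_angle_imu(imu, cbind(numeric(0), numeric(0))),
               "calibration failed")
})

test_that("FSA is invariant to any constant mounting tilt", {
  qe <- quiet_events_50()
  ffw <- foot_flat_windows(qe$events, "imu")
  imu <- qe$trial$imu$foot_L
  ic <- qe$events$imu$L$ic
  f0 <- foot_strike_angle(foot_angle_imu(imu, ffw$L), ic)
  imu2 <- imu
  imu2$euler_pitch <- imu$euler_pitch + 11.3
  f1 <- foot_strike_angle(foot_angle_imu(imu2, ffw$L), ic)
  expect_lt(max(abs(f1 - f0)), 1e-9)
})

test_that("a toes-up strike yields positive FSA in both systems", {
  tab <- quiet_table_50()
  expect_true(all(tab$fsa_omcs > 0))
  expect_true(all(tab$fsa_imu > 0))
})

test_that("noiseless FSA and TC angle match truth within half a degree", {
  g <- quiet_trial_50()
  m <- match_truth(quiet_table_50(), g$truth)
  expect_true(all(abs(m$fsa_omcs - m$fsa_true) <= 0.5))
  expect_true(all(abs(m$fsa_imu - m$fsa_true) <= 0.5))
  expect_true(all(abs(m$foot_angle_tc_omcs - m$foot_angle_tc_true) <= 0.5))
  expect_true(all(abs(m$foot_angle_tc_imu - m$foot_angle_tc_true) <= 0.5))
})

test_that("optical and inertial shank angles agree as calibrated angles", {
  qe <- quiet_events_50()
  ffw <- foot_flat_windows(qe$events, "imu")
  so <- as.numeric(shank_angle(qe$trial$markers$L, "omcs"))
  si <- as.numeric(shank_angle(qe$trial$imu$shank_L, "imu", ffw$L))
  # compare as relative angles about the shared calibration reference: both
  # systems must describe the same shank motion
  so_c <- so - strideval:::.windows_mean(so, ffw$L)
  si_c <- si - 90
  n <- length(so)
  rng <- 200:(n - 200)
  expect_lt(sqrt(mean((so_c[rng] - si_c[rng])^2)), 1)
  # and the vertical re-reference leaves only a small absolute offset
  expect_lt(abs(mean(so[rng] - si[rng])), 1)
})

test_that("shank linear acceleration is the horizontal norm", {
  tr <- list(meta = list(fs_motion = 100),
             imu = list(shank_L = list(accel_global =
               cbind(rep(3, 10), rep(4, 10), 0))))
  expect_equal(shank_linear_acceleration(tr, "L", "imu"), rep(5, 10))
  tr$imu$shank_L$accel_global[] <- 0
  expect_equal(shank_linear_acceleration(tr, "L", "imu"), rep(0, 10))
})

test_that("optical and inertial shank linear acceleration agree", {
  qe <- quiet_events_50()
  ao <- shank_linear_acceleration(qe$trial, "L", "omcs")
  ai <- shank_linear_acceleration(qe$trial, "L", "imu")
  n <- length(ao)
  rng <- 200:(n - 200)
  rel <- sqrt(mean((ao[rng] - ai[rng])^2)) / sqrt(mean(ai[rng]^2))
  expect_lt(rel, 0.05)
})

test_that("treadmill stride length adds belt travel to heel displacement", {
  # stationary heel at ICs, belt 1.0 m/s, stride time 1.2 s -> 1.2 m
  heel <- rep(0.5, 400)
  expect_equal(stride_length(heel, c(100, 220), 1.0, 100), 1.2)
  # overground equivalent: belt 0, heel advanced 1.3 m
  heel2 <- seq(0, 2, length.out = 400)
  ic <- c(50, 310)
  expect_equal(stride_length(heel2, ic, 0, 100),
               heel2[310] - heel2[50])
  expect_error(stride_length(heel, c(1, 2), NULL, 100), "belt")
})

test_that("noiseless stride length matches truth within 1%", {
  g <- quiet_trial_50()
  m <- match_truth(quiet_table_50(), g$truth)
  rel <- abs(m$stride_length_omcs - m$stride_length_true) /
    m$stride_length_true
  expect_lt(max(rel), 0.01)
})

test_that("stride table has one row per matched stride, no NaN when eligible", {
  qe <- quiet_events_50()
  tab <- quiet_table_50()
  pairing_n <- nrow(tab)
  expect_gt(pairing_n, 90)
  el <- tab[tab$eligible, ]
  num <- el[vapply(el, is.numeric, logical(1))]
  expect_false(any(!is.finite(as.matrix(num))))
})

test_that("regression of estimated on true FSA is unbiased", {
  p <- quiet_profile(fsa_sd = 3)
  g <- generate_trial(p, 100, seed = 31)
  cfg <- run_config(list(a = gait_profile(), b = gait_profile()), seed = 1)
  tab <- process_trial(g$trial, cfg)
  m <- match_truth(tab, g$truth)
  expect_gte(nrow(m), 195)
  for (col in c("fsa_omcs", "fsa_imu")) {
    fit <- stats::lm(m[[col]] ~ m$fsa_true)
    expect_gt(coef(fit)[2], 0.95)
    expect_lt(coef(fit)[2], 1.05)
    expect_lt(abs(coef(fit)[1]), 0.5)
  }
})
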