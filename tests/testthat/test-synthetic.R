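# The synthetic generator: determinism, closed-form ground truth, and the
# analytic consistency between channels.

test_that("variance-free generator yields constant ground truth", {
  p <- frozen_profile(fsa_mean = 10)
  g <- generate_trial(p, 5, seed = 1)
  expect_true(all(abs(g$truth$fsa_true - 10) < 1e-12))
  expect_true(all(abs(g$truth$foot_angle_tc_true + p$pushoff_angle) < 1e-12))
})

test_that("identical seeds give identical trials, different seeds differ", {
  p <- gait_profile()
  g1 <- generate_trial(p, 4, seed = 42)
  g2 <- generate_trial(p, 4, seed = 42)
  expect_identical(g1, g2)
  g3 <- generate_trial(p, 4, seed = 43)
  expect_false(identical(g1$trial$markers$L$heel, g3$trial$markers$L$heel))
})

test_that("stride length truth follows belt_speed x stride_time", {
  p <- frozen_profile(belt_speed = 1.0, stride_time_mean = 1.2)
  g <- generate_trial(p, 4, seed = 2)
  expect_equal(g$truth$stride_length_true, rep(1.2, nrow(g$truth)),
               tolerance = 1e-12)
})

test_that("generator rejects degenerate requests", {
  expect_error(generate_trial(gait_profile(), 1, seed = 1), "n_strides")
  expect_error(gait_profile(stride_time_mean = -1), "stride_time")
  expect_error(gait_profile(stance_fraction = 1.2), "stance_fraction")
  expect_error(gait_profile(fs_force = 150), "integer multiple")
})

test_that("foot pitch waveform realizes the stride phase structure", {
  p <- gait_profile()
  w <- foot_pitch_waveform(p, list(stride_time = 1.2, fsa = 10))
  expect_equal(w$angle[1], 10)                      # FSA at initial contact
  fw <- attr(w, "flat_window")
  flat <- w$angle[w$time >= fw[1] & w$time < fw[2]]
  expect_true(all(flat == 0))                       # identically 0 when flat
  tc <- attr(w, "tc_time")
  i_tc <- which.min(abs(w$time - tc))
  expect_equal(w$angle[i_tc], -p$pushoff_angle, tolerance = 1e-3)
  # the rate maximum (mid-swing) lies in swing, not stance
  expect_gt(w$time[which.max(w$rate)], tc)
  expect_equal(attr(w, "midswing_time"), w$time[which.max(w$rate)],
               tolerance = 0.011)
})

test_that("zero-amplitude stride gives a flat zero waveform", {
  p <- gait_profile()
  w <- foot_pitch_waveform(p, list(stride_time = 1.2, fsa = 0, pushoff = 0))
  expect_true(all(abs(w$angle) < 1e-12))
})

test_that("degenerate foot-flat window is rejected", {
  p <- gait_profile()
  expect_error(
    foot_pitch_waveform(p, list(stride_time = 1.2, fsa = 10, descent = 0.6)),
    "foot-flat")
})

test_that("GRF waveform carries closed-form propulsion truth", {
  p <- gait_profile(bpt_fraction = 0.5, body_weight = 800)
  w <- grf_waveform(p, list(stance_time = 0.72, prop_peak = 0.2))
  # analytic: half-sine amplitude A over duration T -> AUC = 2AT/pi
  expect_equal(attr(w, "auc_true"), 2 * 0.2 * 0.36 / pi, tolerance = 1e-12)
  expect_equal(attr(w, "peak_true"), 0.2)
  expect_equal(max(w$ap) / 800, 0.2, tolerance = 1e-4)
  expect_true(all(w$vertical >= 0))
  # double bump: two interior maxima of the vertical profile
  dv <- diff(sign(diff(w$vertical)))
  expect_equal(sum(dv == -2), 2)
  expect_error(grf_waveform(p, list(stance_time = 0.003)), "4 force samples")
})

test_that("force channels are exactly zero during swing", {
  g <- generate_trial(frozen_profile(), 5, seed = 3)
  tu <- g$truth[g$truth$side == "L", ]
  fz <- g$trial$forces$L[, "fz"]
  # middle of the swing of stride 2, far from any stance
  sw0 <- round((tu$tc_time[2] + 0.1) * 1000)
  sw1 <- round((tu$ic_time[3] - 0.1) * 1000)
  expect_true(all(fz[sw0:sw1] == 0))
})

test_that("gyro channel equals the derivative of the Euler pitch channel", {
  g <- quiet_trial_50()
  tu <- g$truth
  lo <- ceiling(min(tu$ic_time) * 100) + 2
  hi <- floor(max(tu$ic_time + 1.0) * 100) - 2
  for (seg in c("foot_L", "foot_R")) {
    d <- differentiate(g$trial$imu[[seg]]$euler_pitch, 100)
    dev <- max(abs(d - g$trial$imu[[seg]]$gyro[, 1])[lo:hi])
    expect_lt(dev, 1)  # deg/s at 100 Hz
  }
})

test_that("written bundles are byte-identical under a fixed seed", {
  p <- gait_profile()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  g1 <- generate_trial(p, 3, seed = 9)
  g2 <- generate_trial(p, 3, seed = 9)
  write_trial(g1$trial, d1, truth = g1$truth)
  write_trial(g2$trial, d2, truth = g2$truth)
  for (f in c("markers.csv", "imu.csv", "forces.csv", "meta.yaml")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("noiseless pipeline recovers truth per stride", {
  g <- quiet_trial_50()
  tab <- quiet_table_50()
  m <- match_truth(tab, g$truth)
  expect_gte(nrow(m), 0.99 * nrow(g$truth))
  expect_true(all(abs(m$fsa_omcs - m$fsa_true) <= 0.5))
  expect_true(all(abs(m$fsa_imu - m$fsa_true) <= 0.5))
})
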