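# Filtering and trimming.

test_that("constant series pass unchanged (unit DC gain)", {
  x <- rep(3.7, 200)
  y <- butterworth_lowpass(x, 100, filter_spec(2, 15))
  expect_equal(y, x, tolerance = 1e-9)
})

test_that("zero-phase filtering attenuates the cutoff sinusoid to 0.5", {
  fs <- 1000
  fc <- 20
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * fc * t)
  y <- butterworth_lowpass(x, fs, filter_spec(4, fc))
  mid <- y[2000:8000]
  # forward-backward filtering squares the magnitude: |H(fc)|^2 = 0.5
  expect_equal(max(abs(mid)), 0.5, tolerance = 0.01)
  # well below the cutoff the passband is flat
  x2 <- sin(2 * pi * (0.1 * fc) * t)
  y2 <- butterworth_lowpass(x2, fs, filter_spec(4, fc))
  expect_gt(max(abs(y2[2000:8000])), 0.99)
})

test_that("filtering twice compounds the attenuation", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 12 * t)
  sp <- filter_spec(2, 15)
  y1 <- butterworth_lowpass(x, fs, sp)
  y2 <- butterworth_lowpass(y1, fs, sp)
  a1 <- max(abs(y1[500:1500]))
  a2 <- max(abs(y2[500:1500]))
  expect_lt(a2, a1 * 0.95)
  expect_equal(a2, a1^2, tolerance = 0.02)
})

test_that("invalid filter requests are rejected", {
  expect_error(butterworth_lowpass(rnorm(100), 100, filter_spec(2, 60)),
               "Nyquist")
  expect_error(butterworth_lowpass(rnorm(5), 100, filter_spec(2, 15)),
               "too short")
  expect_error(filter_spec(3, 15), "order")
})

test_that("the filter plan touches every channel except Euler pitch", {
  g <- generate_trial(frozen_profile(), 5, seed = 6)
  ft <- apply_filter_plan(g$trial)
  expect_identical(ft$imu$foot_L$euler_pitch, g$trial$imu$foot_L$euler_pitch)
  expect_false(identical(ft$imu$foot_L$gyro, g$trial$imu$foot_L$gyro))
  expect_false(identical(ft$markers$L$heel, g$trial$markers$L$heel))
  # noiseless smooth signals barely change over the complete strides
  tu <- g$truth
  rng <- (ceiling(min(tu$ic_time) * 100) + 2):(floor(max(tu$tc_time) * 100) - 2)
  dev <- max(abs(ft$imu$foot_L$gyro[rng, 1] -
                 g$trial$imu$foot_L$gyro[rng, 1]))
  expect_lt(dev, 1)
})

test_that("trimming drops samples consistently at both rates", {
  g <- generate_trial(gait_profile(), 12, seed = 6)
  n_m <- nrow(g$trial$markers$L$heel)
  tt <- trim_recording(g$trial, lead_s = 10, tail_s = 0)
  expect_equal(nrow(tt$markers$L$heel), n_m - 1000)
  expect_equal(nrow(tt$forces$L), (n_m - 1000) * 10)
  t0 <- trim_recording(g$trial, 0, 0)
  expect_identical(t0$markers, g$trial$markers)
  expect_error(trim_recording(g$trial, lead_s = 1e4), "over-trim")
})
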