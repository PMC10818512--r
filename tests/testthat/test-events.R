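# Event detection: analytic cases, truth recovery, alternation, robustness.

test_that("optical IC sits at heel AP position maxima", {
  fs <- 100
  t <- seq(0, 6, by = 1 / fs)
  heel <- sin(2 * pi * t / 1.2)
  ic <- detect_ic_omcs(heel, fs)
  expect_equal(length(ic), 5)            # one per 1.2 s
  # maxima of sin(2 pi t / 1.2) at t = 0.3 + 1.2 k
  expect_equal((ic - 1) / fs, 0.3 + 1.2 * (0:4), tolerance = 0.011)
  expect_error(detect_ic_omcs(rep(1, 500), fs), "no gait detected")
})

test_that("optical TC sits at toe AP position minima", {
  fs <- 100
  t <- seq(0, 6, by = 1 / fs)
  toe <- sin(2 * pi * t / 1.2)
  tc <- detect_tc_omcs(toe, fs)
  expect_equal((tc - 1) / fs, 0.9 + 1.2 * (0:4), tolerance = 0.011)
  expect_error(detect_tc_omcs(rep(0, 500), fs), "no gait detected")
})

test_that("mid-swing peaks are found once per cycle", {
  fs <- 100
  t <- seq(0, 6, by = 1 / fs)
  gml <- 300 * pmax(0, sin(2 * pi * t / 1.2))
  ms <- detect_midswing_imu(gml, fs)
  expect_equal((ms - 1) / fs, 0.3 + 1.2 * (0:4), tolerance = 0.011)
  expect_error(detect_midswing_imu(rep(0, 500), fs), "no gait detected")
})

test_that("IMU IC is the first gyro zero crossing after mid-swing", {
  fs <- 100
  t <- seq(0, 6, by = 1 / fs)
  gml <- 100 * sin(2 * pi * t / 1.2)
  ms <- detect_midswing_imu(gml, fs)
  ic <- detect_ic_imu(gml, ms)
  # crest at 0.3 + 1.2k, next zero a quarter period later at 0.6 + 1.2k
  expect_equal((ic - 1) / fs, 0.6 + 1.2 * seq_along(ic) - 1.2,
               tolerance = 0.011)
  # strictly positive gyro after a crest: stride dropped with warning
  gpos <- c(100 * sin(2 * pi * t[1:100] / 1.2), rep(50, 100), 100, rep(50, 200))
  ms2 <- detect_midswing_imu(gpos, fs)
  expect_warning(ic2 <- detect_ic_imu(gpos, ms2), "dropped")
})

test_that("IMU TC is the acceleration peak between mid-swings, earliest on ties", {
  az <- rep(0, 200)
  az[80] <- 5; az[81] <- 3                 # triangular spike apex at 80
  tc <- detect_tc_imu(az, c(40, 150))
  expect_equal(tc, 80)
  az2 <- rep(0, 200); az2[c(70, 90)] <- 5  # equal maxima: earliest index
  expect_equal(detect_tc_imu(az2, c(40, 150)), 70)
  expect_length(detect_tc_imu(az, c(40, 41)), 0)  # window too short
})

test_that("stride pairing matches shifted lists and discards spurious events", {
  ic_a <- c(100, 220, 340, 460)
  expect_equal(nrow(pair_strides(ic_a, ic_a)), 4)
  p <- pair_strides(ic_a, ic_a + 2)
  expect_equal(nrow(p), 4)
  expect_equal(attr(p, "n_discarded"), 0)
  # one extra spurious event in the second list
  p2 <- pair_strides(ic_a, sort(c(ic_a + 1, 395)))
  expect_equal(nrow(p2), 4)
  expect_equal(attr(p2, "n_discarded"), 1)
  expect_error(pair_strides(numeric(0), ic_a), "not alignable")
})

test_that("noiseless events recover ground truth within sample tolerance", {
  g <- quiet_trial_50()
  ev <- quiet_events_50()$events
  for (s in c("L", "R")) {
    ts <- g$truth[g$truth$side == s, ]
    ict <- ts$ic_time * 100 + 1
    tct <- ts$tc_time * 100 + 1
    expect_lte(max(abs(nearest(ict, ev$omcs[[s]]$ic) - ict)), 1)
    expect_lte(max(abs(nearest(ict, ev$imu[[s]]$ic) - ict)), 1)
    expect_lte(max(abs(nearest(tct, ev$omcs[[s]]$tc) - tct)), 2)
    expect_lte(max(abs(nearest(tct, ev$imu[[s]]$tc) - tct)), 2)
    mst <- ts$midswing_time * 100 + 1
    expect_lte(max(abs(nearest(mst, ev$imu[[s]]$midswing) - mst)), 1)
  }
})

test_that("IC and TC alternate strictly within each side and system", {
  ev <- quiet_events_50()$events
  for (sys in c("omcs", "imu")) for (s in c("L", "R")) {
    cyc <- strideval:::stride_cycles(ev[[sys]][[s]]$ic, ev[[sys]][[s]]$tc)
    expect_true(all(cyc$ic < cyc$tc & cyc$tc < cyc$next_ic))
    expect_true(all(diff(cyc$ic) > 0))
  }
})

test_that("foot-flat windows lie inside the true plateau", {
  g <- quiet_trial_50()
  ev <- quiet_events_50()$events
  for (sys in c("imu", "omcs")) {
    ffw <- foot_flat_windows(ev, sys)
    for (s in c("L", "R")) {
      ts <- g$truth[g$truth$side == s, ]
      checked <- 0
      for (k in seq_len(nrow(ffw[[s]]))) {
        wk <- (ffw[[s]][k, ] - 1) / 100
        j <- which(ts$flat_start_time - 0.1 <= wk[1] &
                     ts$flat_end_time + 0.1 >= wk[2])
        if (length(j) == 0L) next
        j <- j[1]
        checked <- checked + 1
        expect_gte(wk[1], ts$flat_start_time[j] - 1e-9)
        expect_lte(wk[2], ts$flat_end_time[j] + 1e-9)
      }
      expect_gt(checked, 40)
    }
  }
})

test_that("windows are absent without contralateral events", {
  ev <- quiet_events_50()$events
  one_sided <- ev
  one_sided$imu$R <- list(ic = integer(0), tc = integer(0),
                          midswing = integer(0))
  w <- suppressWarnings(foot_flat_windows(one_sided, "imu"))
  expect_equal(nrow(w$L), 0)
  expect_equal(nrow(w$R), 0)
})

test_that("detection stays near-complete under sensor noise", {
  p <- gait_profile(noise_sd_marker = 0.002, noise_sd_gyro = 2,
                    noise_sd_accel = 0.5, noise_sd_euler = 0.2)
  g <- generate_trial(p, 40, seed = 21)
  ft <- apply_filter_plan(g$trial)
  ev <- detect_gait_events(ft)
  tab <- build_stride_table(ft, ev)
  m <- match_truth(tab, g$truth)
  expect_gte(nrow(m), 0.95 * nrow(g$truth))
})
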