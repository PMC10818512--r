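# Propulsion: BPT detection, quadrature, normalization, eligibility.

test_that("BPT is the last braking-to-propulsion crossing", {
  u <- seq(0, 1, by = 0.001)
  ap <- ifelse(u < 0.5, -sin(pi * u / 0.5), sin(pi * (u - 0.5) / 0.5))
  bpt <- detect_bpt(ap)
  expect_equal(bpt, which(u > 0.5)[1], tolerance = 2)
  expect_true(is.na(detect_bpt(-abs(sin(pi * u)))))   # no propulsive phase
  expect_equal(detect_bpt(abs(sin(pi * u)) + 0.01), 1) # positive throughout
})

test_that("propulsion AUC matches the analytic half-sine integral", {
  fs <- 1000
  A <- 0.2
  D <- 0.15
  bw <- 700
  t <- seq(0, D, by = 1 / fs)
  ap <- A * bw * sin(pi * t / D)
  auc <- propulsion_auc(ap, 1, length(ap), bw, fs)
  # closed form 2AD/pi = 0.019099 for A = 0.2 BW over 0.15 s
  expect_equal(auc, 2 * A * D / pi, tolerance = 0.001)
  expect_equal(propulsion_auc(rep(0, 100), 1, 100, bw, fs), 0)
  # doubling body weight halves the normalized integral
  expect_equal(propulsion_auc(ap, 1, length(ap), 2 * bw, fs), auc / 2)
  expect_error(propulsion_auc(ap, 50, 10, bw, fs), "inverted")
})

test_that("propulsion peak is the window maximum in body weights", {
  bw <- 800
  t <- seq(0, 1, by = 0.001)
  ap <- 0.2 * bw * sin(pi * t)
  expect_equal(propulsion_peak(ap, 1, length(ap), bw), 0.2, tolerance = 1e-6)
  ap2 <- c(0.1 * bw * sin(pi * t[1:400] / 0.4),
           0.25 * bw * sin(pi * t[1:601] / 0.6))
  expect_equal(propulsion_peak(ap2, 1, length(ap2), bw), 0.25,
               tolerance = 1e-6)
})

test_that("AUC is additive over a split of the window", {
  set.seed(2)
  ap <- rnorm(501)
  bw <- 700
  full <- propulsion_auc(ap, 1, 501, bw, 1000)
  for (cut in c(2, 57, 250, 499)) {
    parts <- propulsion_auc(ap, 1, cut, bw, 1000) +
      propulsion_auc(ap, cut, 501, bw, 1000)
    expect_equal(parts, full, tolerance = 1e-12)
  }
})

test_that("eligibility separates clean, shared-plate, and crosstalk strides", {
  n <- 3000
  stance <- c(1001, 1800)
  cycle <- c(1001, 2200)
  bump <- function(at, len, amp) {
    f <- numeric(n)
    f[at:(at + len - 1)] <- amp * sin(pi * seq(0, 1, length.out = len))
    f
  }
  own <- bump(1001, 800, 700)
  contra <- bump(1501, 800, 700)   # contralateral on its own plate
  expect_true(stride_eligibility(own, contra, stance, cycle,
                                 list(c(1501, 1800)), 20, 750))
  # both feet on one plate: contralateral load lands on the own plate
  own2 <- own + bump(1501, 800, 700)
  quiet <- numeric(n)
  expect_false(stride_eligibility(own2, quiet, stance, cycle,
                                  list(c(1501, 1800)), 20, 750))
  # the own stance is missing from its plate
  expect_false(stride_eligibility(quiet, contra, stance, cycle,
                                  list(c(1501, 1800)), 20, 750))
  # 5 N crosstalk on the own plate during swing: eligible at the default
  # 20 N threshold, ineligible at threshold 0
  own3 <- own; own3[1900:2100] <- 5
  expect_true(stride_eligibility(own3, contra, stance, cycle,
                                 list(c(1501, 1800)), 20, 750))
  expect_false(stride_eligibility(own3, contra, stance, cycle,
                                  list(c(1501, 1800)), 0, 750))
})

test_that("generator eligibility flags are reproduced from the plates", {
  p <- quiet_profile(both_feet_fraction = 0.12)
  g <- generate_trial(p, 60, seed = 13)
  cfg <- run_config(list(a = gait_profile(), b = gait_profile()), seed = 1)
  tab <- process_trial(g$trial, cfg)
  m <- match_truth(tab, g$truth)
  # interior strides: detected eligibility equals the generator's truth
  interior <- m$stride > 1 & m$stride < max(m$stride)
  expect_true(all(m$eligible[interior] == m$eligible_true[interior]))
  expect_gt(sum(!m$eligible_true), 0)  # the filter was actually exercised
})

test_that("propulsion estimates track truth on eligible strides", {
  g <- quiet_trial_50()
  m <- match_truth(quiet_table_50(), g$truth)
  m <- m[m$eligible & m$eligible_true, ]
  expect_gt(nrow(m), 60)
  expect_gt(cor(m$prop_auc, m$propulsion_auc_true), 0.999)
  expect_gt(cor(m$prop_peak, m$propulsion_peak_true), 0.999)
  # BPT within 2 force samples of the generated lobe boundary
  bpt_true <- ((m$ic_omcs - 1) * 10 + 1) +
    0.5 * (m$tc_omcs - m$ic_omcs) * 10
  expect_lte(max(abs(m$bpt_idx - bpt_true)), 12)  # includes IC rounding
})
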