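# Synthetic treadmill-gait generator.
#
# One stride cycle of one side is parameterized by its duration T, stance
# duration S = stance_fraction * T, the foot strike angle realized at the
# initial contact (IC) that opens the cycle, the plantarflexion depth P
# reached at terminal contact (TC), and the propulsion amplitude of the
# anterior-posterior ground reaction force. Every stream (markers, IMU,
# forces) of a cycle is evaluated from closed-form piecewise polynomials so
# that the channels are mutually consistent and all event landmarks are known
# exactly:
#
#   - foot pitch: apex parabola at IC (gyro crosses zero linearly at IC),
#     C2 quintic blend to the foot-flat plateau (pitch identically zero),
#     quintic push-off blend reaching -P at TC with zero rate/curvature,
#     quintic swing arc whose single rate maximum defines mid-swing;
#   - heel AP velocity: C1 cubic-Hermite spline with zeros exactly at IC
#     (crossing anterior->posterior) and TC (posterior->anterior), a
#     mid-stance plateau at -belt_speed, and zero net displacement per cycle;
#   - toe = heel + foot_length * (cos pitch, sin pitch): rigid foot, so the
#     marker-derived segment angle equals the pitch exactly and the toe AP
#     velocity inherits its TC zero crossing from the heel (pitch rate and
#     curvature vanish at TC);
#   - foot vertical acceleration: three raised-cosine lobes per cycle (peak
#     exactly at TC, swing counter-lobe, landing lobe of half the push-off
#     amplitude) whose integrals close the vertical velocity and position of
#     the heel over the cycle;
#   - ground reaction forces: double-bump vertical profile and a braking
#     half-sine followed by a propulsive half-sine joined at the
#     braking-to-propulsion transition, with closed-form propulsion AUC.

# --- strike-descent profile -------------------------------------------------
# The descent from the foot strike angle to the flat plateau is a
# near-minimal-jerk profile for the boundary conditions
#   theta(0) = A, theta'(0) = 0, theta''(0) free,
#   theta(d) = theta'(d) = theta''(d) = 0.
# The exact minimal-jerk solution is bang-bang (+J then -J, switching at
# d/sqrt(2), J = 6(2+sqrt(2)) A/d^3); here the switch is smoothed by a
# linear jerk ramp of half-width r so the jerk is continuous, which keeps
# the low-pass filters from ringing at the switch while the peak jerk (and
# with it the 100 Hz central-difference discretization error of the gyro
# channel) grows only marginally.
.descent_ramp <- 0.08

# exact polynomial integration of a piecewise polynomial (local power basis
# per segment), with value continuity from `init`
.pw_integrate <- function(breaks, coefs, init = 0) {
  out <- vector("list", length(coefs))
  acc <- init
  for (k in seq_along(coefs)) {
    ci <- c(acc, coefs[[k]] / seq_along(coefs[[k]]))
    out[[k]] <- ci
    acc <- .ppu(ci, 0L, breaks[k + 1L] - breaks[k])
  }
  out
}

.solve_descent <- function(r = .descent_ramp) {
  basisB <- function(t1) {
    breaks <- c(0, t1 - r, t1 + r, 1)
    jerk <- list(1, c(1, -1 / r), -1)  # local-x polynomials
    B2 <- .pw_integrate(breaks, jerk)
    B1 <- .pw_integrate(breaks, B2)
    B0 <- .pw_integrate(breaks, B1)
    endv <- function(pw) .ppu(pw[[3]], 0L, 1 - breaks[3])
    list(breaks = breaks, B0 = B0, B1 = B1, B2 = B2,
         b0 = endv(B0), b1 = endv(B1), b2 = endv(B2))
  }
  t1 <- stats::uniroot(function(t1) {
    b <- basisB(t1)
    b$b2 - b$b1            # theta''(1) = 0 and theta'(1) = 0 simultaneously
  }, c(0.4, 0.95), tol = 1e-12)$root
  b <- basisB(t1)
  J <- -1 / (b$b0 - b$b2 / 2)
  a0 <- -J * b$b2
  # assemble normalized theta segments: theta(u) = 1 + a0 u^2/2 + J B(u),
  # with the quadratic re-expressed in each segment's local coordinate
  segs <- vector("list", 3L)
  for (k in 1:3) {
    bk <- b$breaks[k]
    quad <- a0 / 2 * c(bk^2, 2 * bk, 1)
    cf <- J * b$B0[[k]]
    n <- max(length(cf), 3L)
    cf <- c(cf, numeric(n - length(cf)))
    cf[1:3] <- cf[1:3] + quad
    cf[1] <- cf[1] + 1
    segs[[k]] <- cf
  }
  list(breaks = b$breaks, segs = segs, a0 = a0, J = J)
}
.descent_norm <- .solve_descent()

# curvature and jerk of the descent at IC for amplitude A (deg) over d (s)
descent_curv0 <- function(A, d) .descent_norm$a0 * A / d^2
descent_jerk0 <- function(A, d) .descent_norm$J * A / d^3

# Evaluate the descent and derivatives at times tr in [0, d].
descent_eval <- function(tr, A, d) {
  u <- tr / d
  dn <- .descent_norm
  seg <- findInterval(u, dn$breaks, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L
  seg[seg > 3L] <- 3L
  th <- dth <- ddth <- numeric(length(u))
  for (k in 1:3) {
    i <- seg == k
    if (!any(i)) next
    x <- u[i] - dn$breaks[k]
    th[i] <- .ppu(dn$segs[[k]], 0L, x)
    dth[i] <- .ppu(dn$segs[[k]], 1L, x)
    ddth[i] <- .ppu(dn$segs[[k]], 2L, x)
  }
  list(theta = A * th, dtheta = A * dth / d, ddtheta = A * ddth / d^2)
}

# geometry shared by generator and ground truth
.pitch_f1_frac <- 0.60      # foot-flat end as a fraction of stance
.descent_margin <- 0.02     # s between descent end and contralateral TC

pitch_geometry <- function(stride_time, stance_time, descent = NULL) {
  if (is.null(descent))
    descent <- stance_time - stride_time / 2 - .descent_margin
  f1 <- .pitch_f1_frac * stance_time
  if (descent <= 0 || f1 <= descent)
    stop("foot-flat window has non-positive length for this stride timing")
  if (stride_time <= stance_time)
    stop("swing phase too short for this stride timing")
  list(descent = descent, f1 = f1, stance = stance_time, stride = stride_time)
}

# Push-off blend: the unique degree-6 polynomial with value, rate, curvature
# AND jerk zero at the start of the blend (C3 join to the plateau), and
# value -P with zero rate and curvature at terminal contact. Normalized
# shape q: q(0..3 derivs at 0) = 0, q(1) = 1, q'(1) = q''(1) = 0.
.pushoff_norm <- local({
  cond <- function(k, u) vapply(0:6, function(i)
    if (i < k) 0 else prod(seq.int(i, by = -1L, length.out = k)) * u^(i - k),
    numeric(1))
  A <- rbind(cond(0, 0), cond(1, 0), cond(2, 0), cond(3, 0),
             cond(0, 1), cond(1, 1), cond(2, 1))
  q <- c(solve(A, c(0, 0, 0, 0, 1, 0, 0)), 0)
  # add a multiple of x^4 (1-x)^3 (zero value/rate/curvature at both ends,
  # jerk only at the far end) chosen to minimize the peak jerk of the blend
  b43 <- c(0, 0, 0, 0, 1, -3, 3, -1)
  ug <- seq(0, 1, by = 0.001)
  peak_jerk <- function(l) max(abs(.ppu(q + l * b43, 3L, ug)))
  lam <- stats::optimize(peak_jerk, c(-40, 40))$minimum
  q + lam * b43
})

# Swing arc: quintic from push-off depth at TC to the next foot strike angle
# with zero end rate and the next descent's initial curvature, corrected by
# three vanishing-boundary bump bases so that (a) the jerk at TC matches the
# push-off blend, (b) the jerk at the next IC matches the next descent
# (pitch is C3 across both joins), and (c) the rate maximum (mid-swing)
# sits in the first 55% of the swing.
.swing_peak_u <- 0.45
.swing_b34 <- c(0, 0, 0, 1, -4, 6, -4, 1, 0)     # u^3 (1-u)^4: jerk at 0 only
.swing_b44 <- c(0, 0, 0, 0, 1, -4, 6, -4, 1)     # u^4 (1-u)^4: jerk-neutral

# Pre-IC jerk adapter: over the last `w` seconds of the swing the pitch is
# perturbed by dJ * w^3 * G(x/w), where G is the unique degree-7 shape with
# zero value/rate/curvature/jerk at its start and zero value/rate/curvature
# but unit jerk at its end. This ramps the swing's jerk continuously into
# the next descent's initial jerk without touching the foot strike angle,
# the IC gyro zero crossing, or its slope.
.adapter_G <- c(0, 0, 0, 0, -1 / 6, 1 / 2, -1 / 2, 1 / 6)
.adapter_w <- 0.08

# position (u in (0,1)) of the global maximum of the derivative of the
# polynomial with coefficients cf
.rate_argmax <- function(cf) {
  dcoef <- cf[-1] * seq_along(cf[-1])
  d2coef <- dcoef[-1] * seq_along(dcoef[-1])
  r <- polyroot(d2coef)
  u <- Re(r[abs(Im(r)) < 1e-8])
  u <- u[u > 0 & u < 1]
  cand <- c(u, 1e-9, 1 - 1e-9)
  val <- vapply(cand, function(uu) sum(dcoef * uu^(seq_along(dcoef) - 1L)),
                numeric(1))
  cand[which.max(val)]
}

.swing_coef <- function(stride_time, stance_time, fsa1, pushoff, descent_next) {
  d5 <- stride_time - stance_time
  d4 <- stance_time - .pitch_f1_frac * stance_time
  q <- c(quintic_coef(-pushoff, 0, 0, fsa1, 0,
                      descent_curv0(fsa1, descent_next), d5), 0, 0, 0)
  # match the jerk at TC to the push-off blend (u-units of the swing)
  j0 <- -pushoff * .ppu(.pushoff_norm, 3L, 1) / d4^3 * d5^3
  nu <- (j0 - .ppu(q, 3L, 0)) / 6    # b34 jerk at 0 is 6
  base <- q + nu * .swing_b34
  u_star <- .swing_peak_u
  cf <- base
  for (it in 1:12) {
    kappa <- -.ppu(base, 2L, u_star) / .ppu(.swing_b44, 2L, u_star)
    cf <- base + kappa * .swing_b44
    if (.rate_argmax(cf) <= 0.55 || u_star <= 0.3) break
    u_star <- u_star - 0.03
  }
  cf
}

# Closed-form foot pitch of one cycle. tr: times relative to IC in
# [0, stride_time). Returns theta (deg), dtheta (deg/s), ddtheta (deg/s^2).
pitch_cycle_eval <- function(tr, stride_time, stance_time, fsa0, fsa1, pushoff,
                             descent = NULL, descent_next = NULL) {
  g <- pitch_geometry(stride_time, stance_time, descent)
  if (is.null(descent_next)) descent_next <- g$descent
  d4 <- g$stance - g$f1
  d5 <- stride_time - g$stance
  c4 <- -pushoff * .pushoff_norm
  c5 <- .swing_coef(stride_time, stance_time, fsa1, pushoff, descent_next)

  theta <- numeric(length(tr))
  dtheta <- numeric(length(tr))
  ddtheta <- numeric(length(tr))
  brk <- c(0, g$descent, g$f1, g$stance, stride_time)
  seg <- findInterval(tr, brk, rightmost.closed = FALSE)
  i <- seg == 1L
  if (any(i)) {
    de <- descent_eval(tr[i], fsa0, g$descent)
    theta[i] <- de$theta; dtheta[i] <- de$dtheta; ddtheta[i] <- de$ddtheta
  }
  # segment 2: foot flat, all zero (already initialized)
  i <- seg == 3L
  theta[i] <- poly_eval(c4, tr[i] - g$f1, d4)
  dtheta[i] <- poly_eval(c4, tr[i] - g$f1, d4, 1L)
  ddtheta[i] <- poly_eval(c4, tr[i] - g$f1, d4, 2L)
  i <- seg == 4L
  theta[i] <- poly_eval(c5, tr[i] - g$stance, d5)
  dtheta[i] <- poly_eval(c5, tr[i] - g$stance, d5, 1L)
  ddtheta[i] <- poly_eval(c5, tr[i] - g$stance, d5, 2L)
  # pre-IC jerk adapter over the last stretch of the swing
  w <- min(.adapter_w, 0.25 * d5)
  js <- .ppu(c5, 3L, 1) / d5^3
  dJ <- descent_jerk0(fsa1, descent_next) - js
  ia <- i & tr >= stride_time - w
  if (any(ia)) {
    xi <- (tr[ia] - (stride_time - w)) / w
    theta[ia] <- theta[ia] + dJ * w^3 * .ppu(.adapter_G, 0L, xi)
    dtheta[ia] <- dtheta[ia] + dJ * w^2 * .ppu(.adapter_G, 1L, xi)
    ddtheta[ia] <- ddtheta[ia] + dJ * w * .ppu(.adapter_G, 2L, xi)
  }
  list(theta = theta, dtheta = dtheta, ddtheta = ddtheta)
}

# True mid-swing: the unique interior maximum of the pitch rate during the
# swing arc, located by the real roots of the quartic rate's derivative.
midswing_rel_time <- function(stride_time, stance_time, fsa0, fsa1, pushoff,
                              descent = NULL, descent_next = NULL) {
  g <- pitch_geometry(stride_time, stance_time, descent)
  if (is.null(descent_next)) descent_next <- g$descent
  d5 <- stride_time - g$stance
  c5 <- .swing_coef(stride_time, stance_time, fsa1, pushoff, descent_next)
  # dtheta(u) ~ sum_{i>=1} i c_i u^(i-1); critical points from its derivative
  dcoef <- c5[-1] * seq_along(c5[-1])
  d2coef <- dcoef[-1] * seq_along(dcoef[-1])
  r <- polyroot(d2coef)
  u <- Re(r[abs(Im(r)) < 1e-8])
  u <- u[u > 0 & u < 1]
  cand <- c(u, 1e-9, 1 - 1e-9)
  val <- vapply(cand, function(uu) sum(dcoef * uu^(seq_along(dcoef) - 1L)),
                numeric(1))
  g$stance + cand[which.max(val)] * d5
}

#' Foot-pitch waveform of one synthetic stride
#'
#' Evaluates the generator's sagittal foot-pitch model for a single stride at
#' the motion sample rate: heel strike at the foot strike angle, a smooth
#' descent to the foot-flat plateau (pitch identically zero), a push-off
#' blend reaching `-pushoff` degrees at terminal contact, and a swing arc
#' returning to the next stride's foot strike angle. The waveform is twice
#' continuously differentiable, so the gyroscope channel (its first
#' derivative) is smooth and mid-swing (the rate maximum) is well defined.
#'
#' @param profile A [gait_profile()]; supplies `fs_motion` and
#'   `stance_fraction`.
#' @param stride A list with elements `stride_time` (s), `fsa` (deg),
#'   optionally `fsa_next` (deg, defaults to `fsa`), `pushoff` (deg,
#'   defaults to `profile$pushoff_angle`) and `descent` (s, duration of the
#'   strike-to-flat descent; defaults to the time until the contralateral
#'   terminal contact minus a small margin).
#' @return A data.frame with columns `time` (s, relative to initial contact),
#'   `angle` (deg) and `rate` (deg/s), with attributes `flat_window`
#'   (c(start, end), s), `tc_time` and `midswing_time` (s).
#' @examples
#' p <- gait_profile()
#' w <- foot_pitch_waveform(p, list(stride_time = 1.2, fsa = 10))
#' w$angle[1]   # equals the foot strike angle
#' @export
foot_pitch_waveform <- function(profile, stride) {
  validate_gait_profile(profile)
  stopifnot(is.list(stride), !is.null(stride$stride_time), !is.null(stride$fsa))
  stride_time <- stride$stride_time
  if (stride_time <= 0) stop("stride_time must be positive")
  fsa0 <- stride$fsa
  fsa1 <- if (is.null(stride$fsa_next)) fsa0 else stride$fsa_next
  pushoff <- if (is.null(stride$pushoff)) profile$pushoff_angle else stride$pushoff
  stance_time <- profile$stance_fraction * stride_time
  g <- pitch_geometry(stride_time, stance_time, stride$descent)
  tr <- seq(0, stride_time - 1e-9, by = 1 / profile$fs_motion)
  ev <- pitch_cycle_eval(tr, stride_time, stance_time, fsa0, fsa1, pushoff,
                         g$descent, g$descent)
  out <- data.frame(time = tr, angle = ev$theta, rate = ev$dtheta)
  attr(out, "flat_window") <- c(g$descent, g$f1)
  attr(out, "tc_time") <- stance_time
  attr(out, "midswing_time") <-
    midswing_rel_time(stride_time, stance_time, fsa0, fsa1, pushoff,
                      g$descent, g$descent)
  out
}

# Ground reaction forces over one stance, u = t / stance_time in [0, 1].
# Amplitudes in units of body weight; returns newtons.
grf_eval <- function(u, prop_peak, braking_peak, bpt_frac, body_weight) {
  vert <- 1.1 * sin(pi * u) + 0.28 * sin(3 * pi * u)
  vert[u < 0 | u > 1] <- 0
  vert <- pmax(vert, 0) * body_weight
  ap <- numeric(length(u))
  i <- u >= 0 & u < bpt_frac
  ap[i] <- -braking_peak * sin(pi * u[i] / bpt_frac)
  i <- u >= bpt_frac & u <= 1
  ap[i] <- prop_peak * sin(pi * (u[i] - bpt_frac) / (1 - bpt_frac))
  ap <- ap * body_weight
  list(vertical = vert, ap = ap)
}

#' Ground-reaction-force waveform of one synthetic stance
#'
#' Evaluates the generator's force model for a single stance phase at the
#' force-plate sample rate: a double-bump vertical profile and an
#' anterior-posterior (AP) component that is braking (negative) until the
#' braking-to-propulsion transition (BPT) and a propulsive half-sine from the
#' BPT until terminal contact. The closed-form propulsion truth is attached:
#' for a half-sine of amplitude A (body weights) and duration D the AUC is
#' 2AD/pi (BW s) and the peak is A (BW).
#'
#' @param profile A [gait_profile()]; supplies `fs_force`, `bpt_fraction`,
#'   `braking_ratio` and `body_weight`.
#' @param stride A list with `stance_time` (s) and optionally `prop_peak`
#'   (BW, defaults to `profile$prop_peak_mean`).
#' @return A data.frame with columns `time` (s from initial contact),
#'   `vertical` and `ap` (N), with attributes `auc_true` (BW s), `peak_true`
#'   (BW) and `bpt_time` (s).
#' @examples
#' p <- gait_profile()
#' w <- grf_waveform(p, list(stance_time = 0.72, prop_peak = 0.2))
#' attr(w, "auc_true")  # 2 * 0.2 * 0.36 / pi
#' @export
grf_waveform <- function(profile, stride) {
  validate_gait_profile(profile)
  stopifnot(is.list(stride), !is.null(stride$stance_time))
  stance <- stride$stance_time
  if (stance < 4 / profile$fs_force)
    stop("stance window shorter than 4 force samples")
  A <- if (is.null(stride$prop_peak)) profile$prop_peak_mean else stride$prop_peak
  tr <- seq(0, stance, by = 1 / profile$fs_force)
  f <- grf_eval(tr / stance, A, profile$braking_ratio * A,
                profile$bpt_fraction, profile$body_weight)
  out <- data.frame(time = tr, vertical = f$vertical, ap = f$ap)
  attr(out, "auc_true") <- 2 * A * (1 - profile$bpt_fraction) * stance / pi
  attr(out, "peak_true") <- A
  attr(out, "bpt_time") <- profile$bpt_fraction * stance
  out
}

# Heel AP velocity spline of one cycle: knots (time, value, slope).
heel_vel_knots <- function(stride_time, stance_time, belt_speed) {
  S <- stance_time
  Tt <- stride_time
  g0 <- 1.5 * belt_speed / (0.25 * S)
  g1 <- 1.5 * belt_speed / (0.30 * S)
  tk <- c(0, 0.25 * S, 0.70 * S, S, S + 0.55 * (Tt - S), Tt)
  vk <- c(0, -belt_speed, -belt_speed, 0, NA, 0)
  mk <- c(-g0, 0, 0, g1, 0, -g0)
  # solve the swing-peak value for zero net displacement over the cycle
  d <- diff(tk)
  fixed <- cubic_segment_integral(vk[1], mk[1], vk[2], mk[2], d[1]) +
    (-belt_speed) * d[2] +
    cubic_segment_integral(vk[3], mk[3], vk[4], mk[4], d[3]) +
    d[4]^2 * (mk[4] - 0) / 12 +
    d[5]^2 * (0 - mk[6]) / 12
  vk[5] <- -fixed / ((d[4] + d[5]) / 2)
  list(t = tk, v = vk, m = mk)
}

heel_vel_cycle <- function(tr, stride_time, stance_time, belt_speed) {
  kn <- heel_vel_knots(stride_time, stance_time, belt_speed)
  seg <- findInterval(tr, kn$t, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L
  seg[seg > 5L] <- 5L
  v <- numeric(length(tr))
  a <- numeric(length(tr))
  for (i in 1:5) {
    idx <- seg == i
    if (!any(idx)) next
    d <- kn$t[i + 1] - kn$t[i]
    cf <- cubic_coef(kn$v[i], kn$m[i], kn$v[i + 1], kn$m[i + 1], d)
    v[idx] <- poly_eval(cf, tr[idx] - kn$t[i], d)
    a[idx] <- poly_eval(cf, tr[idx] - kn$t[i], d, 1L)
  }
  list(v = v, a = a)
}

# Vertical foot-sensor acceleration lobes of one cycle, relative to IC.
# Returns a list of lobes (center, width, amp); centers may spill past the
# cycle end (landing lobe), the caller adds them onto the global stream.
accel_lobes <- function(stride_time, stance_time, push_peak) {
  Tsw <- stride_time - stance_time
  wP <- 0.15 * Tsw; wS <- 0.60 * Tsw; wL <- 0.30 * Tsw
  cP <- stance_time; cS <- stance_time + 0.5 * Tsw; cL <- stride_time
  p_int <- push_peak * wP / 2
  s_int <- p_int * (cL - cP) / (cL - cS)
  l_int <- p_int * (cS - cP) / (cL - cS)
  list(
    list(center = cP, width = wP, amp = push_peak),
    list(center = cS, width = wS, amp = -2 * s_int / wS),
    list(center = cL, width = wL, amp = 2 * l_int / wL)
  )
}

# Shank pitch (deg from horizontal walking direction; ~90 = vertical) and its
# time derivatives, as first+second stride harmonics with phases chosen so
# the pitch passes through vertical near the middle of the foot-flat window.
.shank_ph1 <- -0.013
.shank_ph2 <- 1.545
shank_cycle <- function(tr, stride_time, amp1, amp2) {
  w1 <- 2 * pi / stride_time
  w2 <- 4 * pi / stride_time
  a1 <- w1 * tr + .shank_ph1
  a2 <- w2 * tr + .shank_ph2
  psi <- 90 + amp1 * cos(a1) + amp2 * cos(a2)
  dpsi <- -amp1 * w1 * sin(a1) - amp2 * w2 * sin(a2)
  ddpsi <- -amp1 * w1^2 * cos(a1) - amp2 * w2^2 * cos(a2)
  list(psi = psi, dpsi = dpsi, ddpsi = ddpsi)
}

# per-side cycle table used by generate_trial; Gaussian draws are clamped at
# +/- 2.5 SD (joint angles and forces are biologically bounded)
.draw_side_params <- function(profile, K) {
  clamp <- function(x, m, s) pmin(pmax(x, m - 2.5 * s), m + 2.5 * s)
  z1 <- stats::rnorm(K)
  z2 <- stats::rnorm(K)
  rho <- profile$indicator_prop_rho
  fsa <- clamp(stats::rnorm(K, profile$fsa_mean, profile$fsa_sd),
               profile$fsa_mean, profile$fsa_sd)
  pushoff <- pmax(2, clamp(profile$pushoff_angle - profile$pushoff_sd * z1,
                           profile$pushoff_angle, profile$pushoff_sd))
  prop <- pmax(0.02, profile$prop_peak_mean +
                 profile$prop_peak_sd * (rho * z1 + sqrt(1 - rho^2) * z2))
  bias <- stats::rnorm(K, profile$fsa_bias_mean, profile$fsa_bias_sd)
  displaced <- stats::runif(K) < profile$both_feet_fraction
  data.frame(fsa = fsa, pushoff = pushoff, prop = prop,
             bias = bias, displaced = displaced)
}

#' Generate one synthetic treadmill walking trial with exact ground truth
#'
#' Builds mutually consistent marker trajectories (heel, toe, ankle, knee of
#' both sides), foot- and shank-IMU streams (3-axis gyroscope and
#' accelerometer in the sensor frame, gravity-removed acceleration in the
#' gravity-aligned global frame, Euler pitch), and two force plates, for
#' `n_strides` strides per side of a walker described by `profile`. The two
#' sides alternate with a half-cycle phase shift. Identical arguments produce
#' bit-identical output.
#'
#' The returned ground truth records, per side and stride: the true initial
#' contact, terminal contact and mid-swing times, the true foot strike angle,
#' the foot angle at terminal contact, the body-weight-normalized propulsion
#' AUC and peak, the stride length, and whether the stride is eligible for
#' propulsion analysis (ineligible strides have both feet on one plate).
#'
#' @param profile A [gait_profile()].
#' @param n_strides Number of complete strides per side (>= 2).
#' @param seed Integer seed; fixes all stochastic elements.
#' @param subject_id,trial_id Identifiers stored in the trial metadata.
#' @return A list with elements `trial` (a [gait_trial()]) and `truth`
#'   (a data.frame of class `gait_truth`).
#' @seealso [foot_pitch_waveform()], [grf_waveform()], [make_cohort()]
#' @export
generate_trial <- function(profile, n_strides, seed,
                           subject_id = "S01", trial_id = "T01") {
  validate_gait_profile(profile)
  if (n_strides < 2) stop("n_strides must be at least 2 (no complete stride cycle)")
  if (profile$stride_time_mean <= 0) stop("non-positive stride_time")
  set.seed(as.integer(seed))

  n <- as.integer(n_strides)
  K <- n + 3L   # cycles drawn per side (includes warm-up/tail cycles)
  stride_t <- pmin(pmax(stats::rnorm(K, profile$stride_time_mean,
                                     profile$stride_time_sd),
                        0.6 * profile$stride_time_mean),
                   1.6 * profile$stride_time_mean)
  parL <- .draw_side_params(profile, K)
  parR <- .draw_side_params(profile, K)

  c_frac <- profile$stance_fraction
  lead <- 0.8 * stride_t[1]
  L_ic <- lead + c(0, cumsum(stride_t))[seq_len(K + 1L)]  # cycles 0..K-1 starts
  # cycle tables: L cycles 0..n+1 ; R cycles -1..n (half-cycle later than L)
  nL <- n + 2L
  cyc_L <- data.frame(
    start = L_ic[seq_len(nL)],
    dur = stride_t[seq_len(nL)],
    fsa0 = parL$fsa[seq_len(nL)],
    fsa1 = parL$fsa[seq_len(nL) + 1L],
    pushoff = parL$pushoff[seq_len(nL)],
    prop = parL$prop[seq_len(nL)],
    bias = parL$bias[seq_len(nL)],
    displaced = parL$displaced[seq_len(nL)]
  )
  R_ic0 <- L_ic[seq_len(nL - 1L)] + stride_t[seq_len(nL - 1L)] / 2 # cycles 0..n
  R_dur0 <- (stride_t[seq_len(nL - 1L)] + stride_t[seq_len(nL - 1L) + 1L]) / 2
  cyc_R <- data.frame(
    start = c(R_ic0[1] - stride_t[1], R_ic0),
    dur = c(stride_t[1], R_dur0),
    fsa0 = parR$fsa[seq_len(nL)],
    fsa1 = parR$fsa[seq_len(nL) + 1L],
    pushoff = parR$pushoff[seq_len(nL)],
    prop = parR$prop[seq_len(nL)],
    bias = parR$bias[seq_len(nL)],
    displaced = parR$displaced[seq_len(nL)]
  )

  # strike-descent duration per cycle: up to the exact contralateral TC
  # minus a detection margin, bounded away from degenerate values
  clamp_descent <- function(d, dur) {
    pmin(pmax(d, 0.10), .pitch_f1_frac * c_frac * dur - 0.05)
  }
  dL <- cyc_R$start + c_frac * cyc_R$dur - cyc_L$start - .descent_margin
  cyc_L$descent <- clamp_descent(dL, cyc_L$dur)
  dR <- c((c_frac - 0.5) * cyc_R$dur[1],
          cyc_L$start[-nL] + c_frac * cyc_L$dur[-nL] - cyc_R$start[-1]) -
    .descent_margin
  dR[1] <- dR[1] + .descent_margin  # fallback for the lead-in cycle
  cyc_R$descent <- clamp_descent(dR, cyc_R$dur)
  cyc_L$descent_next <- c(cyc_L$descent[-1], cyc_L$descent[nL])
  cyc_R$descent_next <- c(cyc_R$descent[-1], cyc_R$descent[nL])

  D <- L_ic[nL + 1L] + 0.5 * stride_t[nL + 1L]
  fs <- profile$fs_motion
  ratio <- round(profile$fs_force / fs)
  n_m <- floor(D * fs) + 1L
  n_f <- n_m * ratio
  t_m <- (seq_len(n_m) - 1L) / fs
  t_f <- (seq_len(n_f) - 1L) / profile$fs_force

  side_streams <- function(cyc) {
    theta <- rep(cyc$fsa0[1], n_m); dtheta <- numeric(n_m); ddtheta <- numeric(n_m)
    hv <- numeric(n_m); ha <- numeric(n_m)
    az <- numeric(n_m)
    biasang <- numeric(n_m)
    psi <- numeric(n_m); dpsi <- numeric(n_m); ddpsi <- numeric(n_m)
    # pad shank attitude with the first cycle's boundary value
    sc0 <- shank_cycle(0, cyc$dur[1], profile$shank_amp1, profile$shank_amp2)
    psi[] <- sc0$psi
    last_end <- cyc$start[nrow(cyc)] + cyc$dur[nrow(cyc)]
    for (k in seq_len(nrow(cyc))) {
      st <- cyc$start[k]; du <- cyc$dur[k]; S <- c_frac * du
      i0 <- max(1L, ceiling(st * fs - 1e-9) + 1L)
      i1 <- min(n_m, ceiling((st + du) * fs - 1e-9))
      if (i1 < i0) next
      idx <- i0:i1
      tr <- t_m[idx] - st
      pe <- pitch_cycle_eval(tr, du, S, cyc$fsa0[k], cyc$fsa1[k], cyc$pushoff[k],
                             cyc$descent[k], cyc$descent_next[k])
      theta[idx] <- pe$theta; dtheta[idx] <- pe$dtheta; ddtheta[idx] <- pe$ddtheta
      he <- heel_vel_cycle(tr, du, S, profile$belt_speed)
      hv[idx] <- he$v; ha[idx] <- he$a
      sc <- shank_cycle(tr, du, profile$shank_amp1, profile$shank_amp2)
      psi[idx] <- sc$psi; dpsi[idx] <- sc$dpsi; ddpsi[idx] <- sc$ddpsi
      # vertical-acceleration lobes (may spill past the cycle end)
      for (lb in accel_lobes(du, S, profile$accel_push_peak)) {
        j0 <- max(1L, floor((st + lb$center - lb$width / 2) * fs) + 1L)
        j1 <- min(n_m, ceiling((st + lb$center + lb$width / 2) * fs) + 1L)
        if (j1 < j0) next
        jdx <- j0:j1
        az[jdx] <- az[jdx] +
          raised_cosine(t_m[jdx] - st, lb$center, lb$width, lb$amp)
      }
      # phase-locked orientation-output error peaking at this cycle's IC:
      # emulates the transient inaccuracy of the sensor-fusion attitude
      # estimate around heel strike. It perturbs only the Euler pitch
      # channel; the raw gyroscope is unaffected, as on a real sensor.
      if (cyc$bias[k] != 0) {
        wb <- 0.16 * du
        j0 <- max(1L, floor((st - wb / 2) * fs) + 1L)
        j1 <- min(n_m, ceiling((st + wb / 2) * fs) + 1L)
        jdx <- j0:j1
        biasang[jdx] <- biasang[jdx] +
          raised_cosine(t_m[jdx], st, wb, cyc$bias[k])
      }
    }
    # freeze pitch after the last defined cycle end
    tail_idx <- t_m >= last_end
    if (any(tail_idx)) {
      theta[tail_idx] <- theta[max(which(!tail_idx))]
      dtheta[tail_idx] <- 0; ddtheta[tail_idx] <- 0
      hv[tail_idx] <- 0; ha[tail_idx] <- 0
      psi[tail_idx] <- psi[max(which(!tail_idx))]
      dpsi[tail_idx] <- 0; ddpsi[tail_idx] <- 0
    }
    list(theta = theta, dtheta = dtheta, ddtheta = ddtheta,
         heel_v = hv, heel_a = ha, az = az,
         biasang = biasang,
         psi = psi, dpsi = dpsi, ddpsi = ddpsi)
  }

  sL <- side_streams(cyc_L)
  sR <- side_streams(cyc_R)

  h <- 1 / fs
  grav <- 9.81
  build_side <- function(ss, x_lat) {
    heel_y <- -0.1 + cumtrapz_h(ss$heel_v, h)
    heel_z <- 0.03 + cumtrapz_h(cumtrapz_h(ss$az, h), h)
    thr <- ss$theta * pi / 180
    toe_y <- heel_y + profile$foot_length * cos(thr)
    toe_z <- heel_z + profile$foot_length * sin(thr)
    ankle_y <- heel_y + 0.05 * cos(thr) - 0.07 * sin(thr)
    ankle_z <- heel_z + 0.05 * sin(thr) + 0.07 * cos(thr)
    psr <- ss$psi * pi / 180
    knee_y <- ankle_y + profile$shank_length * cos(psr)
    knee_z <- ankle_z + profile$shank_length * sin(psr)

    markers <- list(
      heel = cbind(x = rep(x_lat, n_m), y = heel_y, z = heel_z),
      toe = cbind(x = rep(x_lat, n_m), y = toe_y, z = toe_z),
      ankle = cbind(x = rep(x_lat, n_m), y = ankle_y, z = ankle_z),
      knee = cbind(x = rep(x_lat, n_m), y = knee_y, z = knee_z)
    )

    # foot IMU: global-frame acceleration is gravity-removed linear
    # acceleration of the sensor; sensor frame carries gravity rotated by the
    # (tilted) segment pitch.
    chi <- (ss$theta + profile$mounting_tilt_alpha) * pi / 180
    ay <- ss$heel_a
    azf <- ss$az
    foot <- list(
      gyro = cbind(ml = ss$dtheta, v2 = numeric(n_m), v3 = numeric(n_m)),
      accel_sensor = cbind(ax = numeric(n_m),
                           ay = cos(chi) * ay + sin(chi) * (azf + grav),
                           az = -sin(chi) * ay + cos(chi) * (azf + grav)),
      accel_global = cbind(x = numeric(n_m), y = ay, z = azf),
      euler_pitch = ss$theta + profile$mounting_tilt_alpha + ss$biasang
    )
    # shank IMU: global acceleration consistent with the second derivative of
    # the knee-ankle segment vector (what the optical branch differentiates)
    psr_d <- ss$dpsi * pi / 180
    psr_dd <- ss$ddpsi * pi / 180
    seg_ay <- profile$shank_length *
      (-cos(psr) * psr_d^2 - sin(psr) * psr_dd)
    seg_az <- profile$shank_length *
      (-sin(psr) * psr_d^2 + cos(psr) * psr_dd)
    chs <- (ss$psi - 90 + profile$shank_tilt) * pi / 180
    shank <- list(
      gyro = cbind(ml = ss$dpsi, v2 = numeric(n_m), v3 = numeric(n_m)),
      accel_sensor = cbind(ax = numeric(n_m),
                           ay = cos(chs) * seg_ay + sin(chs) * (seg_az + grav),
                           az = -sin(chs) * seg_ay + cos(chs) * (seg_az + grav)),
      accel_global = cbind(x = numeric(n_m), y = seg_ay, z = seg_az),
      euler_pitch = ss$psi + profile$shank_tilt
    )
    list(markers = markers, foot = foot, shank = shank)
  }

  bL <- build_side(sL, -0.1)
  bR <- build_side(sR, +0.1)

  # force plates: each foot on its own plate unless the stance is displaced
  plate <- list(L = cbind(fx = numeric(n_f), fy = numeric(n_f), fz = numeric(n_f)),
                R = cbind(fx = numeric(n_f), fy = numeric(n_f), fz = numeric(n_f)))
  add_stances <- function(cyc, own, other) {
    for (k in seq_len(nrow(cyc))) {
      st <- cyc$start[k]; S <- c_frac * cyc$dur[k]
      i0 <- max(1L, ceiling(st * profile$fs_force - 1e-9) + 1L)
      i1 <- min(n_f, floor((st + S) * profile$fs_force + 1e-9) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      f <- grf_eval((t_f[idx] - st) / S, cyc$prop[k],
                    profile$braking_ratio * cyc$prop[k],
                    profile$bpt_fraction, profile$body_weight)
      tgt <- if (cyc$displaced[k]) other else own
      plate[[tgt]][idx, "fy"] <<- plate[[tgt]][idx, "fy"] + f$ap
      plate[[tgt]][idx, "fz"] <<- plate[[tgt]][idx, "fz"] + f$vertical
    }
  }
  add_stances(cyc_L, "L", "R")
  add_stances(cyc_R, "R", "L")

  # additive sensor noise
  addn <- function(m, sd) if (sd > 0) m + stats::rnorm(length(m), 0, sd) else m
  for (b in c("bL", "bR")) {
    x <- get(b)
    for (mk in names(x$markers)) x$markers[[mk]] <- addn(x$markers[[mk]],
                                                         profile$noise_sd_marker)
    for (seg in c("foot", "shank")) {
      x[[seg]]$gyro <- addn(x[[seg]]$gyro, profile$noise_sd_gyro)
      x[[seg]]$accel_sensor <- addn(x[[seg]]$accel_sensor, profile$noise_sd_accel)
      x[[seg]]$accel_global <- addn(x[[seg]]$accel_global, profile$noise_sd_accel)
      x[[seg]]$euler_pitch <- addn(x[[seg]]$euler_pitch, profile$noise_sd_euler)
    }
    assign(b, x)
  }
  plate$L <- addn(plate$L, profile$noise_sd_force)
  plate$R <- addn(plate$R, profile$noise_sd_force)

  # ground truth: L strides are cycles 1..n, R strides are cycles 0..n-1,
  # i.e. rows 2..n+1 of each cycle table
  truth_rows <- function(cyc, dis_self, dis_other, side) {
    rows <- 2:(n + 1L)
    S <- c_frac * cyc$dur[rows]
    ms <- vapply(rows, function(k)
      midswing_rel_time(cyc$dur[k], c_frac * cyc$dur[k],
                        cyc$fsa0[k], cyc$fsa1[k], cyc$pushoff[k],
                        cyc$descent[k], cyc$descent_next[k]),
      numeric(1))
    elig <- !dis_self[rows] & !dis_other[rows] & !dis_other[rows - 1L]
    data.frame(
      side = side,
      stride = seq_len(n),
      ic_time = cyc$start[rows],
      tc_time = cyc$start[rows] + S,
      midswing_time = cyc$start[rows] + ms,
      fsa_true = cyc$fsa0[rows],
      flat_start_time = cyc$start[rows] + cyc$descent[rows],
      flat_end_time = cyc$start[rows] + .pitch_f1_frac * S,
      foot_angle_tc_true = -cyc$pushoff[rows],
      propulsion_peak_true = cyc$prop[rows],
      propulsion_auc_true = 2 * cyc$prop[rows] *
        (1 - profile$bpt_fraction) * S / pi,
      stride_length_true = profile$belt_speed * cyc$dur[rows],
      fsa_bias_true = cyc$bias[rows],
      eligible_true = elig
    )
  }
  # contra displacement vectors aligned on cycle-table rows: for an L stride
  # in row k, the overlapping R stances sit in rows k and k-1 of cyc_R (and
  # vice versa), because the R table is offset by one cycle (it starts at -1).
  dis_R_for_L <- c(cyc_R$displaced[-1], FALSE) # R rows sit one later than L rows
  dis_L_for_R <- cyc_L$displaced               # L rows sit one earlier than R rows
  truth <- rbind(
    truth_rows(cyc_L, cyc_L$displaced, dis_R_for_L, "L"),
    truth_rows(cyc_R, cyc_R$displaced, dis_L_for_R, "R")
  )
  class(truth) <- c("gait_truth", "data.frame")

  trial <- gait_trial(
    markers = list(L = bL$markers, R = bR$markers),
    imu = list(foot_L = bL$foot, foot_R = bR$foot,
               shank_L = bL$shank, shank_R = bR$shank),
    forces = plate,
    meta = list(trial_id = trial_id, subject_id = subject_id,
                body_weight = profile$body_weight,
                affected_side = "L",
                fs_motion = profile$fs_motion, fs_force = profile$fs_force,
                belt_speed = profile$belt_speed)
  )
  list(trial = trial, truth = truth)
}
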