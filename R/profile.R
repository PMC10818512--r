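#' Walker profile for the synthetic treadmill-gait generator
#'
#' A `gait_profile` collects every parameter the synthetic generator needs to
#' emulate one subject walking on an instrumented treadmill: belt speed,
#' stride timing and its stride-to-stride variability, the foot-strike angle
#' (FSA) distribution, push-off (plantarflexion) depth, the mounting tilt of
#' the foot-dorsum IMU, sensor noise levels, sample rates, and the propulsion
#' model for the anterior-posterior ground reaction force.
#'
#' Angles are in degrees, times in seconds, forces in newtons, positions in
#' metres. Angular velocity is in deg/s and acceleration in m/s^2. Positive
#' foot pitch means toes up (dorsiflexion); the FSA of a rearfoot strike is
#' therefore positive.
#'
#' @param belt_speed Treadmill belt speed (m/s).
#' @param stride_time_mean,stride_time_sd Mean and SD of the stride
#'   duration (s). The SD is the stride-to-stride variability within a trial.
#' @param fsa_mean,fsa_sd Mean and SD of the per-stride true foot strike
#'   angle (degrees).
#' @param pushoff_angle,pushoff_sd Mean and SD of the plantarflexion
#'   magnitude reached at terminal contact (degrees, positive number).
#' @param stance_fraction Fraction of the stride spent in stance, in (0, 1).
#' @param mounting_tilt_alpha Constant pitch offset of the foot-dorsum IMU
#'   relative to the sole plane (degrees); recovered by foot-flat calibration.
#' @param shank_tilt Constant pitch offset of the shank IMU (degrees).
#' @param body_weight Body weight (N).
#' @param noise_sd_gyro,noise_sd_accel,noise_sd_marker,noise_sd_force,noise_sd_euler
#'   Additive i.i.d. Gaussian noise SDs for the gyroscope (deg/s),
#'   accelerometer (m/s^2), marker positions (m), force plates (N) and the
#'   orientation (Euler pitch) output (degrees).
#' @param fs_motion,fs_force Sample rates of the motion (marker + IMU) and
#'   force streams (Hz). `fs_force` must be an integer multiple of
#'   `fs_motion`.
#' @param foot_length,shank_length Segment lengths (m).
#' @param prop_peak_mean,prop_peak_sd Mean and SD of the per-stride peak
#'   propulsive anterior-posterior GRF, in units of body weight (BW).
#' @param braking_ratio Braking-lobe amplitude as a fraction of the
#'   propulsive amplitude of the same stride.
#' @param bpt_fraction Position of the braking-to-propulsion transition as a
#'   fraction of stance duration, in (0, 1).
#' @param indicator_prop_rho Correlation injected between the per-stride
#'   push-off depth (hence the foot angle at terminal contact) and the
#'   per-stride propulsive peak. Used to exercise the correlation analysis
#'   with a known joint distribution.
#' @param fsa_bias_mean,fsa_bias_sd Mean and SD (degrees) of a per-stride
#'   gait-phase-locked perturbation of the foot IMU pitch that equals the
#'   drawn value exactly at initial contact and vanishes during foot-flat.
#'   This injects a controlled inter-system FSA difference that foot-flat
#'   calibration cannot remove. Defaults are 0 (systems agree).
#' @param accel_push_peak Peak vertical acceleration of the foot sensor at
#'   terminal contact (m/s^2), the landmark used by the IMU TC detector.
#' @param shank_amp1,shank_amp2 First- and second-harmonic amplitudes of the
#'   shank pitch excursion about vertical (degrees).
#' @param both_feet_fraction Fraction of strides in which the contralateral
#'   foot lands on the stance foot's force plate, producing strides that the
#'   eligibility filter must discard.
#'
#' @return An object of class `gait_profile` (a validated named list).
#' @seealso [generate_trial()], [make_cohort()]
#' @examples
#' p <- gait_profile(fsa_mean = 12, fsa_sd = 0)
#' p$fsa_mean
#' @export
gait_profile <- function(belt_speed = 1.0,
                         stride_time_mean = 1.2,
                         stride_time_sd = 0.03,
                         fsa_mean = 7,
                         fsa_sd = 1.2,
                         pushoff_angle = 15,
                         pushoff_sd = 1.5,
                         stance_fraction = 0.70,
                         mounting_tilt_alpha = 25,
                         shank_tilt = 5,
                         body_weight = 750,
                         noise_sd_gyro = 1,
                         noise_sd_accel = 0.3,
                         noise_sd_marker = 0.001,
                         noise_sd_force = 1,
                         noise_sd_euler = 0.1,
                         fs_motion = 100,
                         fs_force = 1000,
                         foot_length = 0.25,
                         shank_length = 0.40,
                         prop_peak_mean = 0.20,
                         prop_peak_sd = 0.03,
                         braking_ratio = 0.75,
                         bpt_fraction = 0.5,
                         indicator_prop_rho = 0.5,
                         fsa_bias_mean = 0,
                         fsa_bias_sd = 0,
                         accel_push_peak = 12,
                         shank_amp1 = 25,
                         shank_amp2 = 8,
                         both_feet_fraction = 0.05) {
  p <- list(
    belt_speed = belt_speed,
    stride_time_mean = stride_time_mean,
    stride_time_sd = stride_time_sd,
    fsa_mean = fsa_mean,
    fsa_sd = fsa_sd,
    pushoff_angle = pushoff_angle,
    pushoff_sd = pushoff_sd,
    stance_fraction = stance_fraction,
    mounting_tilt_alpha = mounting_tilt_alpha,
    shank_tilt = shank_tilt,
    body_weight = body_weight,
    noise_sd_gyro = noise_sd_gyro,
    noise_sd_accel = noise_sd_accel,
    noise_sd_marker = noise_sd_marker,
    noise_sd_force = noise_sd_force,
    noise_sd_euler = noise_sd_euler,
    fs_motion = fs_motion,
    fs_force = fs_force,
    foot_length = foot_length,
    shank_length = shank_length,
    prop_peak_mean = prop_peak_mean,
    prop_peak_sd = prop_peak_sd,
    braking_ratio = braking_ratio,
    bpt_fraction = bpt_fraction,
    indicator_prop_rho = indicator_prop_rho,
    fsa_bias_mean = fsa_bias_mean,
    fsa_bias_sd = fsa_bias_sd,
    accel_push_peak = accel_push_peak,
    shank_amp1 = shank_amp1,
    shank_amp2 = shank_amp2,
    both_feet_fraction = both_feet_fraction
  )
  class(p) <- "gait_profile"
  validate_gait_profile(p)
  p
}

#' @rdname gait_profile
#' @param x A `gait_profile`.
#' @export
validate_gait_profile <- function(x) {
  stopifnot(inherits(x, "gait_profile"))
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (f in names(x)) {
    if (!num1(x[[f]])) stop("profile field '", f, "' must be a finite number")
  }
  if (x$stride_time_mean <= 0) stop("stride_time_mean must be positive")
  if (x$stance_fraction <= 0 || x$stance_fraction >= 1)
    stop("stance_fraction must lie in (0, 1)")
  for (f in c("stride_time_sd", "fsa_sd", "pushoff_sd", "noise_sd_gyro",
              "noise_sd_accel", "noise_sd_marker", "noise_sd_force",
              "noise_sd_euler", "prop_peak_sd", "fsa_bias_sd")) {
    if (x[[f]] < 0) stop("'", f, "' must be non-negative")
  }
  if (x$fs_motion <= 0 || x$fs_force <= 0)
    stop("sample rates must be positive")
  if (abs(x$fs_force / x$fs_motion - round(x$fs_force / x$fs_motion)) > 1e-9)
    stop("fs_force must be an integer multiple of fs_motion")
  if (x$body_weight <= 0) stop("body_weight must be positive")
  if (x$bpt_fraction <= 0 || x$bpt_fraction >= 1)
    stop("bpt_fraction must lie in (0, 1)")
  if (abs(x$indicator_prop_rho) > 1)
    stop("indicator_prop_rho must lie in [-1, 1]")
  if (x$both_feet_fraction < 0 || x$both_feet_fraction > 1)
    stop("both_feet_fraction must lie in [0, 1]")
  invisible(x)
}

#' @export
print.gait_profile <- function(x, ...) {
  cat("<gait_profile>\n")
  cat(sprintf("  belt %.2f m/s, stride %.3f +/- %.3f s, stance %.0f%%\n",
              x$belt_speed, x$stride_time_mean, x$stride_time_sd,
              100 * x$stance_fraction))
  cat(sprintf("  FSA %.1f +/- %.1f deg, push-off %.1f deg, IMU tilt %.1f deg\n",
              x$fsa_mean, x$fsa_sd, x$pushoff_angle, x$mounting_tilt_alpha))
  cat(sprintf("  propulsion peak %.2f +/- %.2f BW, BPT at %.0f%% stance\n",
              x$prop_peak_mean, x$prop_peak_sd, 100 * x$bpt_fraction))
  cat(sprintf("  rates %g / %g Hz, noise gyro %.2g deg/s, marker %.2g m\n",
              x$fs_motion, x$fs_force, x$noise_sd_gyro, x$noise_sd_marker))
  invisible(x)
}
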