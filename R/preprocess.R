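#' Low-pass filter specification
#'
#' Channel-specific zero-phase Butterworth low-pass settings. The default
#' plan used by [apply_filter_plan()] is second order at 15 Hz for angular
#' velocity and marker trajectories, second order at 17 Hz for acceleration,
#' and fourth order at 20 Hz for the force plates.
#'
#' @param order Filter order (2 or 4).
#' @param cutoff Cut-off frequency in Hz.
#' @param zero_phase Apply forward-backward (zero-phase) filtering. The
#'   squared magnitude response then applies, so a sinusoid exactly at the
#'   cut-off is attenuated to 0.5 rather than 1/sqrt(2).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order, cutoff, zero_phase = TRUE) {
  if (!order %in% c(2, 4)) stop("filter order must be 2 or 4")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(order = as.integer(order), cutoff = cutoff,
                 family = "butterworth-lowpass",
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Default channel-to-filter assignment
#'
#' @return A named list of [filter_spec()]s for `gyro`, `accel`, `marker`
#'   and `force` channels.
#' @export
default_filter_plan <- function() {
  list(gyro = filter_spec(2, 15),
       accel = filter_spec(2, 17),
       marker = filter_spec(2, 15),
       force = filter_spec(4, 20))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters a series with a Butterworth low-pass of the given spec. In
#' zero-phase mode the filter is applied forward and backward, which removes
#' phase lag (so event timing is not biased) at the cost of squaring the
#' magnitude response. Edge effects are controlled by odd-reflection padding
#' of length `3 * order` samples.
#'
#' @param x Numeric series (or a matrix, filtered column-wise).
#' @param fs Sample rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered series, same length as the input; DC gain is 1 so
#'   constant series pass unchanged.
#' @export
butterworth_lowpass <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (is.matrix(x))
    return(apply(x, 2, butterworth_lowpass, fs = fs, spec = spec))
  if (spec$cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  n <- length(x)
  if (n <= 3 * spec$order) stop("series too short for this filter order")
  bf <- signal::butter(spec$order, spec$cutoff / (fs / 2), type = "low")
  npad <- 3L * spec$order
  head_pad <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  xp <- c(head_pad, x, tail_pad)
  # steady-state initialization at the boundary value (plus odd-reflection
  # padding) suppresses start-up transients; constants pass exactly
  run <- function(z) as.numeric(signal::filter(bf, z,
                                               init.x = rep(z[1], spec$order),
                                               init.y = rep(z[1], spec$order)))
  y <- run(xp)
  if (spec$zero_phase) y <- rev(run(rev(y)))
  y[npad + seq_len(n)]
}

#' Apply the per-channel filter plan to a whole trial
#'
#' Filters each channel family of a [gait_trial()] with its assigned
#' low-pass spec: gyroscope, accelerometer (both frames), marker
#' trajectories and force plates. The Euler pitch channel is intentionally
#' left unfiltered (it is an orientation output, not a raw inertial
#' channel).
#'
#' @param trial A [gait_trial()].
#' @param plan A named list as from [default_filter_plan()].
#' @return The filtered [gait_trial()].
#' @export
apply_filter_plan <- function(trial, plan = default_filter_plan()) {
  validate_gait_trial(trial)
  fsm <- trial$meta$fs_motion
  fsf <- trial$meta$fs_force
  for (s in c("L", "R")) {
    for (m in .marker_names)
      trial$markers[[s]][[m]] <-
        butterworth_lowpass(trial$markers[[s]][[m]], fsm, plan$marker)
    trial$forces[[s]] <-
      butterworth_lowpass(trial$forces[[s]], fsf, plan$force)
  }
  for (seg in .imu_segments) {
    trial$imu[[seg]]$gyro <-
      butterworth_lowpass(trial$imu[[seg]]$gyro, fsm, plan$gyro)
    trial$imu[[seg]]$accel_sensor <-
      butterworth_lowpass(trial$imu[[seg]]$accel_sensor, fsm, plan$accel)
    trial$imu[[seg]]$accel_global <-
      butterworth_lowpass(trial$imu[[seg]]$accel_global, fsm, plan$accel)
  }
  attr(trial, "filtered") <- TRUE
  trial
}

#' Trim the lead-in and tail of a recording
#'
#' Drops `lead_s` seconds from the start and `tail_s` from the end of every
#' stream, consistently across the motion and force rates (the force stream
#' is trimmed at the rate ratio so the length invariant is preserved).
#'
#' @param trial A [gait_trial()].
#' @param lead_s,tail_s Seconds to drop at each end.
#' @return The trimmed [gait_trial()].
#' @export
trim_recording <- function(trial, lead_s = 0, tail_s = 0) {
  validate_gait_trial(trial)
  if (lead_s < 0 || tail_s < 0) stop("trim durations must be non-negative")
  fsm <- trial$meta$fs_motion
  ratio <- round(trial$meta$fs_force / fsm)
  n_m <- nrow(trial$markers$L$heel)
  drop_head <- round(lead_s * fsm)
  drop_tail <- round(tail_s * fsm)
  if (drop_head + drop_tail >= n_m)
    stop("over-trim: nothing left of the recording")
  keep_m <- seq.int(drop_head + 1L, n_m - drop_tail)
  keep_f <- seq.int(drop_head * ratio + 1L, (n_m - drop_tail) * ratio)
  for (s in c("L", "R")) {
    for (m in .marker_names)
      trial$markers[[s]][[m]] <- trial$markers[[s]][[m]][keep_m, , drop = FALSE]
    trial$forces[[s]] <- trial$forces[[s]][keep_f, , drop = FALSE]
  }
  for (seg in .imu_segments) {
    for (ch in c("gyro", "accel_sensor", "accel_global"))
      trial$imu[[seg]][[ch]] <- trial$imu[[seg]][[ch]][keep_m, , drop = FALSE]
    trial$imu[[seg]]$euler_pitch <- trial$imu[[seg]]$euler_pitch[keep_m]
  }
  validate_gait_trial(trial)
  trial
}
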