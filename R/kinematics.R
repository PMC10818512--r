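# Sagittal-plane kinematics for both systems: segment angles, foot-flat
# calibration, foot strike angle, derivatives, shank linear acceleration,
# stride length, and assembly of the per-stride indicator table.

#' Numerical differentiation by central differences
#'
#' Central differences in the interior, one-sided differences at the edges.
#' `order = 2` applies the first derivative twice (the convention used for
#' angular acceleration: the derivative of the angular velocity).
#'
#' @param x Numeric series.
#' @param fs Sample rate (Hz).
#' @param order 1 (default) or 2.
#' @return Series of the same length; units scale by `fs` per order.
#' @export
differentiate <- function(x, fs, order = 1L) {
  n <- length(x)
  if (n < 3L) stop("series too short to differentiate")
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  if (order == 2L) d <- differentiate(d, fs, 1L)
  d
}

# Sagittal angle (degrees) of the vector from marker b to marker a:
# atan2(vertical component, walking-direction component).
segment_angle <- function(a, b) {
  dy <- a[, 2] - b[, 2]
  dz <- a[, 3] - b[, 3]
  if (any(abs(dy) < 1e-12 & abs(dz) < 1e-12))
    stop("degenerate segment: coincident markers")
  atan2(dz, dy) * 180 / pi
}

# Mean of a series over a set of half-open index windows.
.windows_mean <- function(x, windows) {
  if (is.null(windows) || nrow(windows) == 0L)
    stop("calibration failed: no foot-flat window available")
  idx <- unlist(lapply(seq_len(nrow(windows)), function(k)
    seq.int(windows[k, 1], max(windows[k, 1], windows[k, 2] - 1L))))
  mean(x[idx])
}

# Restrict windows to those starting within the first `n_strides` cycles.
.calib_windows <- function(windows, cycles, n_strides = 10L) {
  if (nrow(cycles) == 0L) return(windows[0, , drop = FALSE])
  lim <- cycles$next_ic[min(nrow(cycles), n_strides)]
  windows[windows[, 1] < lim, , drop = FALSE]
}

#' Marker-based foot angle, calibrated to the foot-flat phase
#'
#' The foot segment is the toe-minus-heel marker vector; its sagittal angle
#' is `atan2(vertical, walking-direction)` in degrees. The angle is zeroed
#' by subtracting its mean over the foot-flat (mid-stance) windows of the
#' first `n_calib` strides, so that a flat foot reads 0 degrees.
#'
#' @param markers One side of the `markers` field of a [gait_trial()] (a
#'   list with `toe` and `heel` n x 3 matrices), filtered.
#' @param calib_windows Two-column matrix of half-open foot-flat index
#'   windows (see [foot_flat_windows()]).
#' @param cycles Optional stride-cycle table used to restrict calibration to
#'   the first `n_calib` strides; when `NULL` all supplied windows are used.
#' @param n_calib Number of leading strides used for calibration.
#' @return An object of class `angle_series`: numeric vector of degrees with
#'   attributes `calibration_offset` (deg), `segment` and `system`.
#' @export
foot_angle_omcs <- function(markers, calib_windows, cycles = NULL,
                            n_calib = 10L) {
  ang <- segment_angle(markers$toe, markers$heel)
  w <- if (is.null(cycles)) calib_windows else
    .calib_windows(calib_windows, cycles, n_calib)
  off <- .windows_mean(ang, w)
  structure(ang - off, calibration_offset = off,
            segment = "foot", system = "omcs", class = "angle_series")
}

#' IMU foot angle from the Euler pitch, foot-flat calibrated
#'
#' The Euler pitch of the foot-dorsum sensor equals the foot angle plus the
#' constant mounting tilt. Subtracting the mean pitch over the foot-flat
#' windows of the first `n_calib` strides removes the tilt: the recovered
#' offset is the mounting angle itself.
#'
#' @param imu One foot stream of a [gait_trial()] (`imu$foot_L` or
#'   `imu$foot_R`).
#' @inheritParams foot_angle_omcs
#' @return An `angle_series` (degrees), `calibration_offset` = recovered
#'   mounting tilt.
#' @export
foot_angle_imu <- function(imu, calib_windows, cycles = NULL, n_calib = 10L) {
  ang <- imu$euler_pitch
  w <- if (is.null(cycles)) calib_windows else
    .calib_windows(calib_windows, cycles, n_calib)
  off <- .windows_mean(ang, w)
  structure(ang - off, calibration_offset = off,
            segment = "foot", system = "imu", class = "angle_series")
}

#' Per-stride foot strike angle
#'
#' The foot strike angle of a stride is the calibrated foot angle at that
#' stride's initial contact, each system using its own IC events. Direct
#' sample lookup, no interpolation; ICs outside the series are dropped.
#'
#' @param angle An `angle_series` (or plain numeric vector, degrees).
#' @param ic IC sample indices from the matching system.
#' @return Numeric vector of FSAs (degrees), one per retained IC; attribute
#'   `ic` holds the retained indices.
#' @export
foot_strike_angle <- function(angle, ic) {
  keep <- ic >= 1L & ic <= length(angle)
  structure(as.numeric(angle)[ic[keep]], ic = ic[keep])
}

#' Shank angle for either system
#'
#' Optical: sagittal angle of the knee-minus-ankle vector (a vertical shank
#' reads 90 degrees). IMU: the shank sensor's Euler pitch, re-referenced so
#' that its mean over the foot-flat calibration windows equals 90 degrees
#' (the shank crosses vertical near mid-stance); this removes the arbitrary
#' shank-sensor mounting offset while preserving within-stride dynamics.
#'
#' @param x For `system = "omcs"`: one side of `markers` (with `knee`,
#'   `ankle`). For `system = "imu"`: one shank IMU stream.
#' @param system `"omcs"` or `"imu"`.
#' @param calib_windows,cycles,n_calib Calibration windows (IMU only), as in
#'   [foot_angle_imu()].
#' @return An `angle_series` (degrees).
#' @export
shank_angle <- function(x, system = c("omcs", "imu"), calib_windows = NULL,
                        cycles = NULL, n_calib = 10L) {
  system <- match.arg(system)
  if (system == "omcs") {
    ang <- segment_angle(x$knee, x$ankle)
    return(structure(ang, calibration_offset = 0,
                     segment = "shank", system = "omcs",
                     class = "angle_series"))
  }
  ang <- x$euler_pitch
  w <- if (is.null(cycles)) calib_windows else
    .calib_windows(calib_windows, cycles, n_calib)
  off <- .windows_mean(ang, w) - 90
  structure(ang - off, calibration_offset = off,
            segment = "shank", system = "imu", class = "angle_series")
}

#' Horizontal-plane shank linear acceleration
#'
#' The Euclidean norm of the two horizontal acceleration components of the
#' shank. Optical: second derivative of the x and y components of the
#' knee-minus-ankle segment vector. IMU: the gravity-aligned global-frame
#' acceleration channels directly.
#'
#' @param trial A filtered [gait_trial()].
#' @param side `"L"` or `"R"`.
#' @param system `"omcs"` or `"imu"`.
#' @return Numeric series (m/s^2).
#' @export
shank_linear_acceleration <- function(trial, side, system = c("omcs", "imu")) {
  system <- match.arg(system)
  fs <- trial$meta$fs_motion
  if (system == "omcs") {
    seg_x <- trial$markers[[side]]$knee[, 1] - trial$markers[[side]]$ankle[, 1]
    seg_y <- trial$markers[[side]]$knee[, 2] - trial$markers[[side]]$ankle[, 2]
    ax <- differentiate(seg_x, fs, 2L)
    ay <- differentiate(seg_y, fs, 2L)
  } else {
    st <- trial$imu[[paste0("shank_", side)]]
    if (is.null(st)) stop("missing shank IMU channel for side ", side)
    ax <- st$accel_global[, 1]
    ay <- st$accel_global[, 2]
  }
  sqrt(ax^2 + ay^2)
}

#' Per-stride treadmill stride length
#'
#' On a treadmill the stride length is the heel's forward displacement
#' between consecutive ipsilateral initial contacts plus the belt travel
#' over the same interval: `(y[ic2] - y[ic1]) + belt_speed * (t2 - t1)`.
#'
#' @param heel_ap Heel AP position (m).
#' @param ic IC sample indices (consecutive ipsilateral).
#' @param belt_speed Belt speed (m/s); an error names the treadmill
#'   convention if missing.
#' @param fs Motion sample rate (Hz).
#' @return Numeric vector of `length(ic) - 1` stride lengths (m).
#' @export
stride_length <- function(heel_ap, ic, belt_speed, fs) {
  if (is.null(belt_speed) || !is.finite(belt_speed))
    stop("belt speed missing: treadmill stride length = heel displacement ",
         "between ICs + belt_speed x stride time")
  if (length(ic) < 2L) return(numeric(0))
  diff(heel_ap[ic]) + belt_speed * diff(ic) / fs
}

# max over the stance window [ic, tc] of a series; NA if the window is bad
.stance_max <- function(x, ic, tc) {
  if (is.na(ic) || is.na(tc) || tc <= ic) return(NA_real_)
  max(x[ic:tc])
}

#' Assemble the per-stride indicator table
#'
#' Matches strides across the two systems and computes, per matched stride
#' and per system: the foot strike angle, the foot and shank angle at
#' terminal contact, the maximum foot/shank angular velocity and angular
#' acceleration over stance (IC to TC), the maximum horizontal shank linear
#' acceleration over stance, and the stride length. Propulsion measures are
#' added by [propulsion_for_strides()] via [run_validation()], or can be
#' merged manually.
#'
#' @param trial A filtered [gait_trial()].
#' @param events A `gait_events` object from [detect_gait_events()].
#' @param n_calib Number of leading strides whose foot-flat windows
#'   calibrate the angles (default 10).
#' @return A data.frame of class `stride_table`, one row per matched stride.
#' @export
build_stride_table <- function(trial, events, n_calib = 10L) {
  validate_gait_trial(trial)
  fs <- trial$meta$fs_motion
  ffw <- list(omcs = foot_flat_windows(events, "omcs"),
              imu = foot_flat_windows(events, "imu"))
  rows <- list()
  for (s in c("L", "R")) {
    cyc <- list(omcs = stride_cycles(events$omcs[[s]]$ic, events$omcs[[s]]$tc),
                imu = stride_cycles(events$imu[[s]]$ic, events$imu[[s]]$tc))
    if (nrow(cyc$omcs) == 0L || nrow(cyc$imu) == 0L) next
    pairing <- pair_strides(cyc$omcs$ic, cyc$imu$ic)
    if (nrow(pairing) == 0L) next

    foot_ang <- list(
      omcs = foot_angle_omcs(trial$markers[[s]], ffw$omcs[[s]],
                             cyc$omcs, n_calib),
      imu = foot_angle_imu(trial$imu[[paste0("foot_", s)]], ffw$imu[[s]],
                           cyc$imu, n_calib))
    shank_ang <- list(
      omcs = shank_angle(trial$markers[[s]], "omcs"),
      imu = shank_angle(trial$imu[[paste0("shank_", s)]], "imu",
                        ffw$imu[[s]], cyc$imu, n_calib))
    foot_vel <- list(omcs = differentiate(as.numeric(foot_ang$omcs), fs),
                     imu = trial$imu[[paste0("foot_", s)]]$gyro[, 1])
    shank_vel <- list(omcs = differentiate(as.numeric(shank_ang$omcs), fs),
                      imu = trial$imu[[paste0("shank_", s)]]$gyro[, 1])
    foot_acc <- lapply(foot_vel, differentiate, fs = fs)
    shank_acc <- lapply(shank_vel, differentiate, fs = fs)
    linacc <- list(omcs = shank_linear_acceleration(trial, s, "omcs"),
                   imu = shank_linear_acceleration(trial, s, "imu"))
    heel_ap <- trial$markers[[s]]$heel[, 2]

    tab <- data.frame(
      subject_id = trial$meta$subject_id %||% NA_character_,
      trial_id = trial$meta$trial_id %||% NA_character_,
      side = s,
      stride = seq_len(nrow(pairing))
    )
    for (sys in c("omcs", "imu")) {
      idx <- if (sys == "omcs") pairing$idx_a else pairing$idx_b
      ic <- cyc[[sys]]$ic[idx]
      tc <- cyc[[sys]]$tc[idx]
      nic <- cyc[[sys]]$next_ic[idx]
      fa <- as.numeric(foot_ang[[sys]])
      sa <- as.numeric(shank_ang[[sys]])
      tab[[paste0("ic_", sys)]] <- ic
      tab[[paste0("tc_", sys)]] <- tc
      tab[[paste0("fsa_", sys)]] <- fa[ic]
      tab[[paste0("foot_angle_tc_", sys)]] <- fa[tc]
      tab[[paste0("shank_angle_tc_", sys)]] <- sa[tc]
      tab[[paste0("max_foot_angvel_", sys)]] <-
        mapply(.stance_max, ic, tc, MoreArgs = list(x = foot_vel[[sys]]))
      tab[[paste0("max_shank_angvel_", sys)]] <-
        mapply(.stance_max, ic, tc, MoreArgs = list(x = shank_vel[[sys]]))
      tab[[paste0("max_foot_angacc_", sys)]] <-
        mapply(.stance_max, ic, tc, MoreArgs = list(x = foot_acc[[sys]]))
      tab[[paste0("max_shank_angacc_", sys)]] <-
        mapply(.stance_max, ic, tc, MoreArgs = list(x = shank_acc[[sys]]))
      tab[[paste0("max_shank_linacc_", sys)]] <-
        mapply(.stance_max, ic, tc, MoreArgs = list(x = linacc[[sys]]))
      tab[[paste0("stride_length_", sys)]] <-
        heel_ap[nic] - heel_ap[ic] + trial$meta$belt_speed * (nic - ic) / fs
    }
    rows[[s]] <- tab
  }
  if (length(rows) == 0L) {
    warning("empty stride set")
    out <- data.frame()
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  class(out) <- c("stride_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
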