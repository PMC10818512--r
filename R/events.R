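# Gait event detection for both measurement systems.
#
# Optical (OMCS) events follow the coordinate-based treadmill method: initial
# contact (IC) where the heel marker's anterior-posterior velocity crosses
# zero in the posterior direction, terminal contact (TC) where the toe
# marker's AP velocity crosses zero in the anterior direction. IMU events:
# mid-swing at the maximum mediolateral angular velocity, IC at the first
# zero crossing of the mediolateral angular velocity after mid-swing, TC at
# the peak gravity-removed vertical acceleration between mid-swing events.

# Fractional zero-crossing positions (1-based sample units) with hysteresis:
# a crossing only counts if the series exceeded +/- `hysteresis` (away from
# zero on the approach side) since the previous accepted crossing.
.zero_crossings <- function(v, direction, hysteresis = 0) {
  n <- length(v)
  if (n < 2L) return(numeric(0))
  if (direction == "down") v <- -v  # reduce to up-crossings of -v
  out <- numeric(0)
  armed <- FALSE
  low <- -abs(hysteresis)
  for (i in seq_len(n - 1L)) {
    if (v[i] <= low) armed <- TRUE
    if (armed && v[i] < 0 && v[i + 1L] >= 0 && (v[i + 1L] > 0 || v[i] < 0)) {
      out <- c(out, i + v[i] / (v[i] - v[i + 1L]))
      armed <- hysteresis == 0
    }
  }
  out
}

#' Detect initial contacts from the heel marker (optical system)
#'
#' IC is the instant the anterior-posterior heel velocity crosses zero in
#' the posterior direction (anterior-to-posterior), i.e. at the forward-most
#' heel position. Velocity is obtained by central differences; crossings are
#' localized by linear interpolation and rounded to the nearest sample.
#' Sub-threshold jitter crossings are suppressed by requiring the velocity
#' to exceed `min_speed` between accepted crossings.
#'
#' @param heel_ap Heel AP position series (m), already low-pass filtered.
#' @param fs Motion sample rate (Hz).
#' @param min_speed Hysteresis threshold (m/s).
#' @return Integer vector of IC sample indices.
#' @export
detect_ic_omcs <- function(heel_ap, fs, min_speed = 0.1) {
  v <- differentiate(heel_ap, fs)
  cr <- .zero_crossings(v, "down", hysteresis = min_speed)
  if (length(cr) == 0L) stop("no gait detected")
  as.integer(round(cr))
}

#' Detect terminal contacts from the toe marker (optical system)
#'
#' TC is the instant the anterior-posterior toe velocity crosses zero in the
#' anterior direction (posterior-to-anterior), i.e. at the rearmost toe
#' position. Mirror of [detect_ic_omcs()].
#'
#' @inheritParams detect_ic_omcs
#' @param toe_ap Toe AP position series (m).
#' @return Integer vector of TC sample indices.
#' @export
detect_tc_omcs <- function(toe_ap, fs, min_speed = 0.1) {
  v <- differentiate(toe_ap, fs)
  cr <- .zero_crossings(v, "up", hysteresis = min_speed)
  if (length(cr) == 0L) stop("no gait detected")
  as.integer(round(cr))
}

#' Detect mid-swing events from mediolateral angular velocity
#'
#' Mid-swing is the prominent positive peak of the mediolateral (pitch-axis)
#' angular velocity, one per gait cycle. Peaks below `prominence` are
#' ignored and accepted peaks must be separated by at least
#' `min_stride_time`. Works on any mediolateral angular-velocity series: the
#' foot gyroscope channel, or the differentiated marker-based foot angle for
#' the optical branch.
#'
#' @param gyro_ml Mediolateral angular velocity (deg/s), filtered.
#' @param fs Motion sample rate (Hz).
#' @param min_stride_time Minimum separation between peaks (s).
#' @param prominence Minimum peak height (deg/s).
#' @return Integer vector of mid-swing sample indices.
#' @export
detect_midswing_imu <- function(gyro_ml, fs, min_stride_time = 0.4,
                                prominence = 50) {
  n <- length(gyro_ml)
  if (n < 3L) stop("no gait detected")
  i <- 2:(n - 1L)
  is_peak <- gyro_ml[i] >= gyro_ml[i - 1L] & gyro_ml[i] >= gyro_ml[i + 1L] &
    gyro_ml[i] >= prominence
  cand <- i[is_peak]
  if (length(cand) == 0L) stop("no gait detected")
  # greedy selection by height with a minimum-separation guard
  cand <- cand[order(gyro_ml[cand], decreasing = TRUE)]
  minsep <- min_stride_time * fs
  keep <- integer(0)
  for (k in cand) if (all(abs(k - keep) >= minsep)) keep <- c(keep, k)
  sort(keep)
}

#' Detect initial contacts from the foot gyroscope (IMU system)
#'
#' For each mid-swing event, IC is the first zero crossing of the
#' mediolateral angular velocity after that mid-swing (linear-interpolated,
#' rounded to the nearest sample). A stride with no crossing before the next
#' mid-swing is dropped with a warning.
#'
#' @param gyro_ml Mediolateral angular velocity (deg/s), filtered.
#' @param midswing Mid-swing indices from [detect_midswing_imu()].
#' @return Integer vector of IC sample indices (one per usable mid-swing).
#' @export
detect_ic_imu <- function(gyro_ml, midswing) {
  n <- length(gyro_ml)
  bounds <- c(midswing, n)
  out <- integer(0)
  dropped <- 0L
  for (k in seq_along(midswing)) {
    i0 <- midswing[k]
    i1 <- bounds[k + 1L]
    if (i1 - i0 < 2L) { dropped <- dropped + 1L; next }
    seg <- gyro_ml[i0:i1]
    cr <- .zero_crossings(seg, "down")
    if (length(cr) == 0L) { dropped <- dropped + 1L; next }
    out <- c(out, as.integer(round(cr[1])) + i0 - 1L)
  }
  if (dropped > 0L)
    warning(dropped, " stride(s) dropped: no gyro zero crossing after mid-swing")
  out
}

#' Detect terminal contacts from vertical acceleration (IMU system)
#'
#' For each pair of consecutive mid-swing events, TC is the sample with the
#' maximum gravity-removed vertical acceleration strictly between them (ties
#' resolve to the earliest index). Windows shorter than 3 samples are
#' dropped.
#'
#' @param accel_z Gravity-removed vertical acceleration of the foot sensor
#'   (m/s^2), filtered.
#' @param midswing Mid-swing indices.
#' @return Integer vector of TC sample indices.
#' @export
detect_tc_imu <- function(accel_z, midswing) {
  out <- integer(0)
  if (length(midswing) < 2L) return(out)
  for (k in seq_len(length(midswing) - 1L)) {
    idx <- (midswing[k] + 1L):(midswing[k + 1L] - 1L)
    if (length(idx) < 3L) next
    out <- c(out, idx[which.max(accel_z[idx])])
  }
  out
}

#' Detect all gait events of a trial, per system and side
#'
#' Runs the optical and inertial event detectors independently on both
#' sides. The optical branch uses the heel/toe AP velocity crossings for
#' IC/TC and the differentiated marker-based foot angle for mid-swing; the
#' inertial branch uses the foot gyroscope and the gravity-removed vertical
#' acceleration.
#'
#' @param trial A filtered [gait_trial()] (see [apply_filter_plan()]).
#' @param min_stride_time,prominence Detector guards, see
#'   [detect_midswing_imu()].
#' @return An object of class `gait_events`: a nested list
#'   `events$<system>$<side>` with elements `ic`, `tc`, `midswing` (sample
#'   indices), plus `fs`.
#' @export
detect_gait_events <- function(trial, min_stride_time = 0.4, prominence = 50) {
  validate_gait_trial(trial)
  fs <- trial$meta$fs_motion
  out <- list(omcs = list(), imu = list(), fs = fs)
  for (s in c("L", "R")) {
    heel_ap <- trial$markers[[s]]$heel[, 2]
    toe_ap <- trial$markers[[s]]$toe[, 2]
    ang <- segment_angle(trial$markers[[s]]$toe, trial$markers[[s]]$heel)
    angvel <- differentiate(ang, fs)
    ms_o <- detect_midswing_imu(angvel, fs, min_stride_time, prominence)
    out$omcs[[s]] <- list(ic = detect_ic_omcs(heel_ap, fs),
                          tc = detect_tc_omcs(toe_ap, fs),
                          midswing = ms_o)
    seg <- paste0("foot_", s)
    gml <- trial$imu[[seg]]$gyro[, 1]
    az <- trial$imu[[seg]]$accel_global[, 3]
    ms_i <- detect_midswing_imu(gml, fs, min_stride_time, prominence)
    out$imu[[s]] <- list(ic = detect_ic_imu(gml, ms_i),
                         tc = detect_tc_imu(az, ms_i),
                         midswing = ms_i)
  }
  class(out) <- "gait_events"
  out
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events>\n")
  for (sys in c("omcs", "imu")) for (s in c("L", "R"))
    cat(sprintf("  %s %s: %d IC, %d TC, %d mid-swing\n", sys, s,
                length(x[[sys]][[s]]$ic), length(x[[sys]][[s]]$tc),
                length(x[[sys]][[s]]$midswing)))
  invisible(x)
}

# Per-side gait cycles of one system: strides [ic_k, ic_{k+1}) containing
# exactly one TC. Returns a data.frame(ic, tc, next_ic).
stride_cycles <- function(ic, tc) {
  if (length(ic) < 2L) return(data.frame(ic = integer(0), tc = integer(0),
                                         next_ic = integer(0)))
  rows <- lapply(seq_len(length(ic) - 1L), function(k) {
    tck <- tc[tc > ic[k] & tc < ic[k + 1L]]
    if (length(tck) != 1L) return(NULL)
    data.frame(ic = ic[k], tc = tck, next_ic = ic[k + 1L])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(ic = integer(0), tc = integer(0), next_ic = integer(0)))
  do.call(rbind, rows)
}

#' Foot-flat windows per side
#'
#' The foot-flat phase of one side is the part of its stance between the
#' contralateral terminal contact and the contralateral mid-swing (the foot
#' is flat on the belt while the other leg swings past). Windows are clipped
#' to the stance of the ipsilateral side; strides with missing contralateral
#' events yield no window.
#'
#' @param events A `gait_events` object from [detect_gait_events()].
#' @param system `"imu"` or `"omcs"`: which system's events to use.
#' @return A list with elements `L` and `R`, each a two-column matrix
#'   (`start`, `end`) of half-open sample-index windows.
#' @export
foot_flat_windows <- function(events, system = c("imu", "omcs")) {
  system <- match.arg(system)
  ev <- events[[system]]
  out <- list()
  for (s in c("L", "R")) {
    contra <- if (s == "L") "R" else "L"
    cyc <- stride_cycles(ev[[s]]$ic, ev[[s]]$tc)
    ctc <- ev[[contra]]$tc
    cms <- ev[[contra]]$midswing
    win <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
    if (nrow(cyc) > 0L) {
      for (k in seq_len(nrow(cyc))) {
        ct <- ctc[ctc > cyc$ic[k] & ctc < cyc$tc[k]]
        if (length(ct) == 0L) next
        ct <- ct[1]
        cm <- cms[cms > ct]
        if (length(cm) == 0L) next
        cm <- cm[1]
        a <- max(ct, cyc$ic[k])
        b <- min(cm, cyc$tc[k])
        if (b > a) win <- rbind(win, c(a, b))
      }
    }
    if (nrow(win) == 0L)
      warning("no foot-flat window found for side ", s, " (", system, ")")
    out[[s]] <- win
  }
  out
}

#' Pair strides detected by the two systems
#'
#' Greedy nearest-neighbour matching of IC events across systems: candidate
#' pairs closer than half the median stride time are accepted in order of
#' increasing time difference, each event used at most once. Unmatched
#' events are discarded (their count is reported as an attribute).
#'
#' @param ic_a,ic_b IC sample indices of the two systems (same time base).
#' @return A data.frame with columns `idx_a`, `idx_b` (positions within the
#'   input vectors), `ic_a`, `ic_b`; attribute `n_discarded` counts unmatched
#'   events.
#' @export
pair_strides <- function(ic_a, ic_b) {
  if (length(ic_a) == 0L || length(ic_b) == 0L) stop("systems not alignable")
  tol <- 0.5 * stats::median(diff(ic_a))
  if (!is.finite(tol) || tol <= 0) tol <- Inf
  cand <- expand.grid(idx_a = seq_along(ic_a), idx_b = seq_along(ic_b))
  cand$d <- abs(ic_a[cand$idx_a] - ic_b[cand$idx_b])
  cand <- cand[cand$d <= tol, , drop = FALSE]
  cand <- cand[order(cand$d), , drop = FALSE]
  used_a <- logical(length(ic_a))
  used_b <- logical(length(ic_b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ia <- cand$idx_a[r]; ib <- cand$idx_b[r]
    if (!used_a[ia] && !used_b[ib]) {
      keep[r] <- TRUE
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
    }
  }
  m <- cand[keep, c("idx_a", "idx_b"), drop = FALSE]
  if (nrow(m) == 0L) stop("systems not alignable")
  m <- m[order(m$idx_a), , drop = FALSE]
  out <- data.frame(idx_a = m$idx_a, idx_b = m$idx_b,
                    ic_a = ic_a[m$idx_a], ic_b = ic_b[m$idx_b])
  attr(out, "n_discarded") <- (length(ic_a) - nrow(out)) +
    (length(ic_b) - nrow(out))
  out
}
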