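#' Synchronized gait trial container
#'
#' A `gait_trial` bundles the three time-synchronized measurement streams of
#' one walking trial, each kept at its native sample rate:
#'
#' * `markers`: per side (`L`, `R`), matrices `heel`, `toe`, `ankle`, `knee`
#'   of size n x 3 (columns x, y, z in metres) in the optical global frame
#'   (z vertical, y walking direction, x lateral), at `fs_motion`;
#' * `imu`: per segment (`foot_L`, `foot_R`, `shank_L`, `shank_R`), matrices
#'   `gyro` (deg/s, column 1 = mediolateral pitch axis), `accel_sensor` and
#'   `accel_global` (m/s^2; the global-frame channel is gravity-removed
#'   linear acceleration), and a numeric `euler_pitch` (degrees), at
#'   `fs_motion`;
#' * `forces`: per plate (`L`, `R`), matrices with columns `fx`, `fy` (AP,
#'   positive = propulsive) and `fz` (vertical) in newtons at `fs_force`;
#' * `meta`: `trial_id`, `subject_id`, `body_weight` (N), `affected_side`,
#'   `fs_motion`, `fs_force`, `belt_speed` (m/s).
#'
#' Time is carried implicitly as sample index over rate; the force stream
#' must be exactly `fs_force / fs_motion` times longer than the motion
#' streams.
#'
#' @param markers,imu,forces,meta See description.
#' @return A validated object of class `gait_trial`.
#' @seealso [generate_trial()], [read_trial()], [write_trial()]
#' @export
gait_trial <- function(markers, imu, forces, meta) {
  x <- structure(list(markers = markers, imu = imu, forces = forces,
                      meta = meta),
                 class = "gait_trial")
  validate_gait_trial(x)
  x
}

#' @rdname gait_trial
#' @param x A `gait_trial`.
#' @export
validate_gait_trial <- function(x) {
  stopifnot(inherits(x, "gait_trial"))
  m <- x$meta
  for (f in c("body_weight", "fs_motion", "fs_force"))
    if (is.null(m[[f]]) || !is.finite(m[[f]]))
      stop("metadata incomplete: missing '", f, "'")
  if (m$body_weight <= 0) stop("metadata incomplete: body_weight must be > 0")
  ratio <- m$fs_force / m$fs_motion
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("fs_force must be an integer multiple of fs_motion")
  n_m <- nrow(x$markers$L$heel)
  if (is.null(n_m) || n_m < 1L) stop("empty trial")
  for (s in c("L", "R")) {
    for (mk in c("heel", "toe", "ankle", "knee")) {
      mm <- x$markers[[s]][[mk]]
      if (is.null(mm) || nrow(mm) != n_m || ncol(mm) != 3L)
        stop("desynchronized streams: marker ", s, "/", mk)
      if (!all(is.finite(mm))) stop("non-finite marker values: ", s, "/", mk)
    }
  }
  for (seg in c("foot_L", "foot_R", "shank_L", "shank_R")) {
    st <- x$imu[[seg]]
    if (is.null(st)) stop("incomplete bundle: missing IMU stream ", seg)
    for (ch in c("gyro", "accel_sensor", "accel_global"))
      if (nrow(st[[ch]]) != n_m)
        stop("desynchronized streams: imu ", seg, "/", ch)
    if (length(st$euler_pitch) != n_m)
      stop("desynchronized streams: imu ", seg, "/euler_pitch")
  }
  n_f <- nrow(x$forces$L)
  if (is.null(n_f) || n_f != n_m * round(ratio) || nrow(x$forces$R) != n_f)
    stop("desynchronized streams: force length must be motion length x ",
         round(ratio))
  invisible(x)
}

#' @export
print.gait_trial <- function(x, ...) {
  n_m <- nrow(x$markers$L$heel)
  cat("<gait_trial> ", x$meta$subject_id, "/", x$meta$trial_id, "\n", sep = "")
  cat(sprintf("  %d motion samples @ %g Hz (%.1f s), %d force samples @ %g Hz\n",
              n_m, x$meta$fs_motion, n_m / x$meta$fs_motion,
              nrow(x$forces$L), x$meta$fs_force))
  cat(sprintf("  body weight %.0f N, belt %.2f m/s, affected side %s\n",
              x$meta$body_weight, x$meta$belt_speed, x$meta$affected_side))
  invisible(x)
}

#' Duration of a trial in seconds (motion stream)
#' @param trial A [gait_trial()].
#' @export
trial_duration <- function(trial) {
  nrow(trial$markers$L$heel) / trial$meta$fs_motion
}
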