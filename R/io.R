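# Trial bundle I/O: comma-separated text with one header row, '.' decimal,
# one file per stream, plus a YAML metadata file. Numbers are written with
# 17 significant digits so a write/read round trip is value-exact.

.write_num_csv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  cols <- lapply(df, function(x) sprintf("%.17g", x))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
}

.marker_names <- c("heel", "toe", "ankle", "knee")
.imu_segments <- c("foot_L", "foot_R", "shank_L", "shank_R")

#' Write a trial bundle to disk
#'
#' Serializes a [gait_trial()] (and optionally its ground truth) to a
#' directory of plain comma-separated files: `markers.csv` (24 columns,
#' `<side>_<marker>_<axis>` in metres), `imu.csv` (10 columns per segment:
#' 3-axis gyro in deg/s, 3-axis sensor-frame and gravity-aligned global-frame
#' acceleration in m/s^2, Euler pitch in degrees), `forces.csv` (`fx`, `fy`
#' AP, `fz` vertical per plate, N), `meta.yaml`, and `truth.csv` when a truth
#' table is supplied. Writing the same trial twice yields identical bytes.
#'
#' @param trial A [gait_trial()].
#' @param path Directory to create/fill.
#' @param truth Optional ground-truth data.frame from [generate_trial()].
#' @return `path`, invisibly.
#' @seealso [read_trial()]
#' @export
write_trial <- function(trial, path, truth = NULL) {
  validate_gait_trial(trial)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  mk <- list()
  for (s in c("L", "R")) for (m in .marker_names) for (a in 1:3)
    mk[[paste(s, m, c("x", "y", "z")[a], sep = "_")]] <-
      trial$markers[[s]][[m]][, a]
  .write_num_csv(as.data.frame(mk), file.path(path, "markers.csv"))

  im <- list()
  for (seg in .imu_segments) {
    st <- trial$imu[[seg]]
    for (a in 1:3) {
      im[[paste0(seg, "_gyro_", a)]] <- st$gyro[, a]
      im[[paste0(seg, "_accel_sensor_", a)]] <- st$accel_sensor[, a]
      im[[paste0(seg, "_accel_global_", a)]] <- st$accel_global[, a]
    }
    im[[paste0(seg, "_euler_pitch")]] <- st$euler_pitch
  }
  .write_num_csv(as.data.frame(im), file.path(path, "imu.csv"))

  fo <- list()
  for (s in c("L", "R")) for (cc in c("fx", "fy", "fz"))
    fo[[paste("plate", s, cc, sep = "_")]] <- trial$forces[[s]][, cc]
  .write_num_csv(as.data.frame(fo), file.path(path, "forces.csv"))

  yaml::write_yaml(trial$meta, file.path(path, "meta.yaml"))
  if (!is.null(truth))
    utils::write.csv(truth, file.path(path, "truth.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a trial bundle from disk
#'
#' Inverse of [write_trial()]: reads the stream files of a bundle directory,
#' validates stream lengths, rates and metadata, and returns a
#' [gait_trial()]. If `truth.csv` is present it is attached as attribute
#' `"truth"`.
#'
#' @param path Bundle directory written by [write_trial()] (or following the
#'   same layout).
#' @return A validated [gait_trial()].
#' @export
read_trial <- function(path) {
  need <- c("markers.csv", "imu.csv", "forces.csv", "meta.yaml")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop("incomplete bundle: missing ", f)
  mk <- utils::read.csv(file.path(path, "markers.csv"))
  im <- utils::read.csv(file.path(path, "imu.csv"))
  fo <- utils::read.csv(file.path(path, "forces.csv"))
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  if (is.null(meta$body_weight)) stop("metadata incomplete: missing body_weight")

  markers <- list()
  for (s in c("L", "R")) {
    markers[[s]] <- list()
    for (m in .marker_names) {
      cols <- paste(s, m, c("x", "y", "z"), sep = "_")
      if (!all(cols %in% names(mk)))
        stop("incomplete bundle: marker columns for ", s, "/", m)
      markers[[s]][[m]] <- as.matrix(mk[cols])
      colnames(markers[[s]][[m]]) <- c("x", "y", "z")
    }
  }
  imu <- list()
  for (seg in .imu_segments) {
    g <- paste0(seg, "_gyro_", 1:3)
    as_ <- paste0(seg, "_accel_sensor_", 1:3)
    ag <- paste0(seg, "_accel_global_", 1:3)
    ep <- paste0(seg, "_euler_pitch")
    if (!all(c(g, as_, ag, ep) %in% names(im)))
      stop("incomplete bundle: IMU columns for ", seg)
    imu[[seg]] <- list(gyro = unname(as.matrix(im[g])),
                       accel_sensor = unname(as.matrix(im[as_])),
                       accel_global = unname(as.matrix(im[ag])),
                       euler_pitch = im[[ep]])
    colnames(imu[[seg]]$gyro) <- c("ml", "v2", "v3")
    colnames(imu[[seg]]$accel_sensor) <- c("ax", "ay", "az")
    colnames(imu[[seg]]$accel_global) <- c("x", "y", "z")
  }
  forces <- list()
  for (s in c("L", "R")) {
    cols <- paste("plate", s, c("fx", "fy", "fz"), sep = "_")
    if (!all(cols %in% names(fo)))
      stop("incomplete bundle: force columns for plate ", s)
    forces[[s]] <- as.matrix(fo[cols])
    colnames(forces[[s]]) <- c("fx", "fy", "fz")
  }
  trial <- gait_trial(markers = markers, imu = imu, forces = forces,
                      meta = meta)
  tf <- file.path(path, "truth.csv")
  if (file.exists(tf)) {
    tr <- utils::read.csv(tf)
    class(tr) <- c("gait_truth", "data.frame")
    attr(trial, "truth") <- tr
  }
  trial
}
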