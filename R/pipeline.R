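# End-to-end orchestration: simulate/read -> trim -> filter -> events ->
# kinematics -> kinetics -> agreement + correlation reports, with a run
# manifest for stride bookkeeping.

#' Run configuration for the validation pipeline
#'
#' @param profiles List of [gait_profile()]s, one per synthetic subject
#'   (ignored when `input_dirs` is given). Names become subject ids.
#' @param input_dirs Optional character vector of trial-bundle directories
#'   to read instead of simulating.
#' @param n_strides Strides per side to simulate per subject.
#' @param seed Master seed; per-subject seeds are derived deterministically.
#' @param filter_plan Per-channel filter plan, see [default_filter_plan()].
#' @param min_stride_time,prominence Event-detector guards.
#' @param crosstalk_threshold Force-plate threshold (N) for eligibility.
#' @param calib_strides Leading strides used for foot-flat calibration
#'   (must be >= 1).
#' @param trim_lead,trim_tail Seconds trimmed from each recording.
#' @param out_dir Optional output directory for reports.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(profiles = NULL, input_dirs = NULL, n_strides = 50,
                       seed = 1, filter_plan = default_filter_plan(),
                       min_stride_time = 0.4, prominence = 50,
                       crosstalk_threshold = 20, calib_strides = 10,
                       trim_lead = 0, trim_tail = 0, out_dir = NULL) {
  if (calib_strides < 1) stop("calibration stride count must be >= 1")
  if (is.null(profiles) && is.null(input_dirs))
    stop("run_config needs profiles or input_dirs")
  if (!is.null(profiles)) {
    if (is.null(names(profiles)))
      names(profiles) <- sprintf("S%02d", seq_along(profiles))
    if (anyDuplicated(names(profiles))) stop("duplicate subject ids")
    lapply(profiles, validate_gait_profile)
  }
  structure(list(profiles = profiles, input_dirs = input_dirs,
                 n_strides = n_strides, seed = as.integer(seed),
                 filter_plan = filter_plan,
                 min_stride_time = min_stride_time, prominence = prominence,
                 crosstalk_threshold = crosstalk_threshold,
                 calib_strides = calib_strides,
                 trim_lead = trim_lead, trim_tail = trim_tail,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file may contain: `profile` (named fields overriding [gait_profile()]
#' defaults), `n_subjects`, `n_strides`, `seed`, `filters` (named entries
#' `gyro`/`accel`/`marker`/`force`, each with `order` and `cutoff`),
#' `detector` (`min_stride_time`, `prominence`, `crosstalk_threshold`),
#' `calib_strides`, `trim_lead`, `trim_tail`, `out_dir`, `input_dirs`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- do.call(gait_profile, y$profile %||% list())
  plan <- default_filter_plan()
  for (ch in names(y$filters %||% list())) {
    f <- y$filters[[ch]]
    plan[[ch]] <- filter_spec(f$order %||% plan[[ch]]$order,
                              f$cutoff %||% plan[[ch]]$cutoff)
  }
  det <- y$detector %||% list()
  profiles <- if (is.null(y$input_dirs))
    cohort_profiles(y$n_subjects %||% 12, seed = y$seed %||% 1, base = base)
  else NULL
  run_config(profiles = profiles, input_dirs = y$input_dirs,
             n_strides = y$n_strides %||% 50, seed = y$seed %||% 1,
             filter_plan = plan,
             min_stride_time = det$min_stride_time %||% 0.4,
             prominence = det$prominence %||% 50,
             crosstalk_threshold = det$crosstalk_threshold %||% 20,
             calib_strides = y$calib_strides %||% 10,
             trim_lead = y$trim_lead %||% 0, trim_tail = y$trim_tail %||% 0,
             out_dir = y$out_dir)
}

#' Draw a cohort of subject profiles around a base profile
#'
#' Subject-level parameter variation for multi-subject simulations: per
#' subject, the mean FSA, stride time, belt speed and body weight are drawn
#' around the base profile's values (FSA mean SD 3 deg, stride time SD
#' 0.08 s, belt speed SD 0.1 m/s, body weight SD 80 N).
#'
#' @param n_subjects Number of subjects.
#' @param seed Seed for the subject-level draws.
#' @param base Base [gait_profile()]; per-stride parameters are inherited.
#' @return Named list of [gait_profile()]s.
#' @export
cohort_profiles <- function(n_subjects = 12, seed = 1, base = gait_profile()) {
  set.seed(as.integer(seed))
  out <- list()
  for (i in seq_len(n_subjects)) {
    p <- base
    p$fsa_mean <- stats::rnorm(1, base$fsa_mean, 3)
    p$stride_time_mean <- max(0.8, stats::rnorm(1, base$stride_time_mean, 0.08))
    p$belt_speed <- max(0.5, stats::rnorm(1, base$belt_speed, 0.1))
    p$body_weight <- max(400, stats::rnorm(1, base$body_weight, 80))
    out[[sprintf("S%02d", i)]] <- p
  }
  out
}

#' Simulate a multi-subject cohort
#'
#' One synthetic trial per profile, with deterministic per-subject seeds
#' derived from `seed`. With `out_dir` set, bundles are written to disk and
#' the paths returned; otherwise the trials are returned in memory.
#'
#' @param profiles Named list of [gait_profile()]s (>= 2 subjects).
#' @param seed Master seed.
#' @param n_strides Strides per side per subject.
#' @param out_dir Optional directory for trial bundles.
#' @return List of `list(trial, truth)` per subject, or bundle paths.
#' @export
make_cohort <- function(profiles, seed, n_strides = 50, out_dir = NULL) {
  if (length(profiles) < 2L) stop("a cohort needs at least 2 profiles")
  if (is.null(names(profiles)))
    names(profiles) <- sprintf("S%02d", seq_along(profiles))
  if (anyDuplicated(names(profiles))) stop("duplicate subject ids")
  out <- list()
  for (i in seq_along(profiles)) {
    id <- names(profiles)[i]
    g <- generate_trial(profiles[[i]], n_strides,
                        seed = as.integer(seed) + 7919L * i,
                        subject_id = id, trial_id = "T01")
    if (is.null(out_dir)) {
      out[[id]] <- g
    } else {
      p <- file.path(out_dir, id)
      write_trial(g$trial, p, truth = g$truth)
      out[[id]] <- p
    }
  }
  out
}

#' Process one trial into a stride table
#'
#' Trim, filter, detect events on both branches independently, build the
#' per-stride indicator table, and attach the propulsion measures and
#' eligibility flags.
#'
#' @param trial A [gait_trial()] (raw).
#' @param config A [run_config()] (detector and filter settings are used).
#' @return A `stride_table`.
#' @export
process_trial <- function(trial, config = run_config(profiles = list(gait_profile()))) {
  if (config$trim_lead > 0 || config$trim_tail > 0)
    trial <- trim_recording(trial, config$trim_lead, config$trim_tail)
  trial <- apply_filter_plan(trial, config$filter_plan)
  ev <- detect_gait_events(trial, config$min_stride_time, config$prominence)
  tab <- build_stride_table(trial, ev, config$calib_strides)
  propulsion_for_strides(trial, tab, config$crosstalk_threshold)
}

#' Run the full validation analysis
#'
#' Executes the pipeline per subject (simulate or read, trim, filter,
#' events, kinematics, kinetics), pools the stride tables, and computes the
#' agreement statistics of the IMU-based vs optical FSA (stride-by-stride
#' Bland-Altman, ICC(3,1), repeatability coefficient; within-subject
#' variants) and the indicator-vs-propulsion correlation tables. A manifest
#' records configuration, seed, stride counts and exclusion tallies. With
#' `config$out_dir` set, all reports are written as CSV/JSON/text; on any
#' stage failure partial outputs are removed and the stage is named in the
#' error.
#'
#' @param config A [run_config()].
#' @return List of class `validation_report`: `stride_table`, `agreement`
#'   (pooled Bland-Altman, `icc`, `rc`), `within_subject`, `correlations`,
#'   `manifest`.
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  wrote <- character(0)
  fail <- function(stage, e) {
    for (f in wrote) unlink(f)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  tabs <- list()
  n_subj <- if (!is.null(config$input_dirs)) length(config$input_dirs)
            else length(config$profiles)
  for (i in seq_len(n_subj)) {
    trial <- tryCatch({
      if (!is.null(config$input_dirs)) read_trial(config$input_dirs[i])
      else generate_trial(config$profiles[[i]], config$n_strides,
                          seed = config$seed + 7919L * i,
                          subject_id = names(config$profiles)[i],
                          trial_id = "T01")$trial
    }, error = function(e) fail("input", e))
    tabs[[i]] <- tryCatch(process_trial(trial, config),
                          error = function(e) fail("processing", e))
    rm(trial)
  }
  stride_tab <- do.call(rbind, tabs)
  class(stride_tab) <- c("stride_table", "data.frame")
  if (nrow(stride_tab) == 0L) stop("stage 'processing' failed: no strides")

  agreement <- tryCatch({
    ba <- bland_altman(stride_tab$fsa_imu, stride_tab$fsa_omcs)
    icc <- icc_3_1(stride_tab$fsa_imu, stride_tab$fsa_omcs)
    list(bland_altman = ba, icc = icc,
         rc = repeatability_coefficient(ba$differences))
  }, error = function(e) fail("agreement", e))

  within <- tryCatch(
    if (length(unique(stride_tab$subject_id)) >= 2L)
      within_subject_agreement(stride_tab$subject_id, stride_tab$fsa_imu,
                               stride_tab$fsa_omcs)
    else NULL,
    error = function(e) fail("within_subject", e))

  correlations <- tryCatch(
    if (sum(stride_tab$eligible) >= 10L) correlation_tables(stride_tab)
    else NULL,
    error = function(e) fail("correlation", e))

  manifest <- list(
    package_version = as.character(utils::packageVersion("strideval")),
    seed = config$seed,
    n_subjects = n_subj,
    n_strides_config = config$n_strides,
    calib_strides = config$calib_strides,
    detector = list(min_stride_time = config$min_stride_time,
                    prominence = config$prominence,
                    crosstalk_threshold = config$crosstalk_threshold),
    strides_matched = nrow(stride_tab),
    strides_eligible = sum(stride_tab$eligible),
    strides_excluded_plate = sum(!stride_tab$eligible)
  )

  rep <- structure(list(stride_table = stride_tab, agreement = agreement,
                        within_subject = within, correlations = correlations,
                        manifest = manifest),
                   class = "validation_report")

  if (!is.null(out_dir)) {
    tryCatch({
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      w <- function(x, f) {
        p <- file.path(out_dir, f)
        utils::write.csv(x, p, row.names = FALSE)
        wrote <<- c(wrote, p)
      }
      w(stride_tab, "stride_table.csv")
      if (!is.null(correlations)) w(correlations, "correlations.csv")
      if (!is.null(within)) w(within$per_subject, "within_subject.csv")
      mp <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      wrote <- c(wrote, mp)
      sp <- file.path(out_dir, "summary.txt")
      writeLines(format_validation_summary(rep), sp)
      wrote <- c(wrote, sp)
    }, error = function(e) fail("output", e))
  }
  rep
}

#' Plain-text summary of a validation report
#' @param rep A `validation_report`.
#' @return Character vector of summary lines.
#' @export
format_validation_summary <- function(rep) {
  ba <- rep$agreement$bland_altman
  icc <- rep$agreement$icc
  out <- c(
    sprintf("%d strides included for stride-by-stride validity analysis.",
            ba$n),
    sprintf("ICC(3,1) = %.2f, 95%%CI: [%.2f; %.2f] (%s).",
            icc$icc, icc$ci_low, icc$ci_high, classify_correlation(icc$icc)),
    sprintf(paste0("Mean IMU-optical FSA difference %.1f degrees, 95%% limits",
                   " of agreement %.1f to %.1f degrees."),
            ba$mean_diff, ba$loa_low, ba$loa_high),
    sprintf("Repeatability coefficient %.1f degrees.", rep$agreement$rc))
  if (!is.null(rep$within_subject)) {
    ws <- rep$within_subject
    out <- c(out, sprintf(
      paste0("Within-subject: mean difference %.1f (SD %.1f) degrees, mean",
             " repeatability coefficient %.1f (SD %.1f) degrees."),
      ws$mean_diff_mean, ws$mean_diff_sd, ws$rc_mean, ws$rc_sd))
  }
  out <- c(out, sprintf(
    "%d of %d matched strides eligible for propulsion analysis.",
    rep$manifest$strides_eligible, rep$manifest$strides_matched))
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(paste0("  ", format_validation_summary(x)), sep = "\n")
  invisible(x)
}
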