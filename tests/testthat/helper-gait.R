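# Shared fixtures: noise-free profiles and memoized synthetic trials, so the
# expensive generation/processing steps run once per test session.

quiet_profile <- function(...) {
  gait_profile(noise_sd_gyro = 0, noise_sd_accel = 0, noise_sd_marker = 0,
               noise_sd_force = 0, noise_sd_euler = 0, ...)
}

# all per-stride variation off: every stride identical
frozen_profile <- function(...) {
  quiet_profile(fsa_sd = 0, stride_time_sd = 0, pushoff_sd = 0,
                prop_peak_sd = 0, both_feet_fraction = 0, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a quiet 50-stride trial with default per-stride variation, processed
quiet_trial_50 <- function() cached("qt50", generate_trial(quiet_profile(), 50, seed = 7))
quiet_events_50 <- function() cached("qe50", {
  g <- quiet_trial_50()
  ft <- apply_filter_plan(g$trial)
  list(trial = ft, events = detect_gait_events(ft))
})
quiet_table_50 <- function() cached("qtab50", {
  qe <- quiet_events_50()
  propulsion_for_strides(qe$trial, build_stride_table(qe$trial, qe$events))
})

# Match truth strides (per side) to stride-table rows by nearest optical IC,
# within a small tolerance. Returns the merged data.frame.
match_truth <- function(tab, truth, fs = 100, tol = 2) {
  out <- NULL
  for (s in c("L", "R")) {
    ts <- truth[truth$side == s, , drop = FALSE]
    tt <- tab[tab$side == s, , drop = FALSE]
    if (nrow(tt) == 0L) next
    idx <- vapply(ts$ic_time * fs + 1, function(t)
      which.min(abs(tt$ic_omcs - t)), integer(1))
    ok <- abs(tt$ic_omcs[idx] - (ts$ic_time * fs + 1)) <= tol
    out <- rbind(out, data.frame(ts[ok, , drop = FALSE],
                                 tt[idx[ok], , drop = FALSE]))
  }
  out
}

# nearest element of v for each x
nearest <- function(x, v) vapply(x, function(t) v[which.min(abs(v - t))],
                                 numeric(1))
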