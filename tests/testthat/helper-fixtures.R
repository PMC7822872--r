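# Shared fixtures built in code.

# Perfectly regular beat train at a given rate.
regular_beats <- function(bpm = 66, duration = 60, phase = 0.5) {
  t <- seq(phase, duration, by = 60 / bpm)
  event_series(t, "r_wave", duration = duration)
}

# Brute-force nearest-event assignment: exhaustive all-pairs minimum with
# the same earlier-event tie rule. Independent oracle for assign_nearest.
brute_force_nearest <- function(taps, events) {
  vapply(taps, function(tp) {
    d <- abs(tp - events)
    which(d == min(d))[1L]  # earliest index among ties
  }, integer(1L))
}

# Minimal long-format event CSV on disk; returns the path.
write_fixture_csv <- function(lines, dir = tempdir()) {
  path <- tempfile("events", tmpdir = dir, fileext = ".csv")
  writeLines(c("subject_id,group,condition,stream,time_s", lines), path)
  path
}

# Hand-built cohort_table rows for pipeline tests that need exact z values.
metrics_row <- function(subject_id, group, condition, z,
                        n_taps = 30L, valid = TRUE, ttc_z = NA) {
  data.frame(subject_id = subject_id, group = group, condition = condition,
             trial_index = trial_index(condition), z = z,
             observed_sd = 0.1, n_taps = n_taps, n_beats = 66L,
             n_events = 66L, heart_rate = 66, counting_accuracy = 0.5,
             mean_delay = 0, confidence = 50, intensity = 50,
             difficulty = 50, valid = valid, stringsAsFactors = FALSE)
}

make_table <- function(df) {
  attr(df, "exclusions") <- data.frame(subject_id = character(),
                                       condition = character(),
                                       reason = character())
  class(df) <- c("cohort_table", class(df))
  df
}
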