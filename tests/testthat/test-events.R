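test_that("event_series validates ordering and window", {
  es <- event_series(c(0, 1.5, 59.9), "tap")
  expect_s3_class(es, "event_series")
  expect_equal(length(es), 3L)
  expect_silent(event_series(numeric(0), "tone"))  # empty is permitted
  expect_error(event_series(c(1, 1), "tap"), "strictly increasing")
  expect_error(event_series(c(2, 1), "tap"), "strictly increasing")
  expect_error(event_series(c(-0.1, 1), "tap"), "\\[0, duration\\]")
  expect_error(event_series(c(1, 61), "tap"), "\\[0, duration\\]")
})

test_that("trial_record enforces required streams and trial coding", {
  r <- event_series(c(1, 2, 3), "r_wave")
  taps <- event_series(c(1.1, 2.2), "tap")
  tr <- trial_record("s1", "healthy", "guessing", list(r, taps))
  expect_equal(tr$trial_index, 1L)
  expect_equal(trial_index(c("guessing", "no_guessing", "breath_hold")),
               1:3)
  expect_true(is.na(trial_index("tone")))
  expect_error(trial_record("s1", "healthy", "tone", list(r, taps)),
               "tone stream")
  expect_error(trial_record("s1", "healthy", "no_guessing", list(taps)),
               "r_wave stream")
})

test_that("read_event_table parses a small file into trial records", {
  path <- write_fixture_csv(c(
    "s1,healthy,guessing,tap,1.5",
    "s1,healthy,guessing,tap,2.5",
    "s1,healthy,guessing,tap,3.5",
    "s1,healthy,guessing,r_wave,1.0",
    "s1,healthy,guessing,r_wave,2.0",
    "s1,healthy,guessing,r_wave,3.0"
  ))
  recs <- read_event_table(path)
  expect_length(recs, 1L)
  expect_equal(length(recs[[1]]$streams$tap), 3L)
  expect_equal(recs[[1]]$streams$r_wave$times, c(1, 2, 3))
  expect_equal(nrow(attr(recs, "rejected")), 0L)
})

test_that("malformed rows are rejected with their line numbers", {
  path <- write_fixture_csv(c(
    "s1,healthy,guessing,tap,1.5",
    "s1,healthy,guessing,tap,abc",
    "s1,healthy,guessing,r_wave,2.0",
    "s1,healthy,guessing,r_wave,999"
  ))
  expect_warning(recs <- read_event_table(path), "line")
  rej <- attr(recs, "rejected")
  expect_equal(rej$line, c(3L, 5L))  # header is line 1
  expect_match(rej$reason[1], "non-numeric")
  expect_match(rej$reason[2], "outside")
})

test_that("missing columns error; empty file yields empty collection", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,stream,time_s", "s1,healthy,tap,1"), bad)
  expect_error(read_event_table(bad), "condition")
  empty <- write_fixture_csv(character(0))
  recs <- read_event_table(empty)
  expect_length(recs, 0L)
})

test_that("write/read round-trip preserves times to 1 microsecond", {
  set.seed(42)
  r <- event_series(sort(runif(40, 0, 60)), "r_wave")
  taps <- event_series(sort(runif(15, 0, 60)), "tap")
  rec <- trial_record("s7", "sud", "breath_hold", list(r, taps))
  path <- tempfile(fileext = ".csv")
  write_event_table(list(rec), path)
  back <- read_event_table(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$streams$r_wave$times, r$times, tolerance = 1e-6)
  expect_equal(back[[1]]$streams$tap$times, taps$times, tolerance = 1e-6)
})

test_that("estimate_ptt takes the median R-to-pulse delay", {
  r <- event_series(1:6, "r_wave", duration = 10)
  ppg <- event_series(1:6 + 0.2, "ppg_foot", duration = 10)
  est <- estimate_ptt(r, ppg)
  expect_equal(est$value, 0.2)
  expect_false(est$is_fallback)
  expect_equal(est$n_pairs, 6L)
  # median arithmetic on uneven delays
  est2 <- estimate_ptt(c(1, 2, 3), c(1.18, 2.20, 3.26), min_pairs = 3L)
  expect_equal(est2$value, 0.20)
  expect_false(est2$is_fallback)
})

test_that("estimate_ptt falls back to 200 ms on insufficient pairs", {
  est <- estimate_ptt(c(1, 2, 3), numeric(0))
  expect_identical(est$value, 0.200)
  expect_true(est$is_fallback)
  # fewer matches than min_pairs is also a fallback
  est2 <- estimate_ptt(c(1, 2, 3), c(1.2, 2.2, 3.2), min_pairs = 5L)
  expect_true(est2$is_fallback)
  expect_identical(est2$value, 0.200)
  # pulses with no preceding R wave within max_lag are unmatched
  est3 <- estimate_ptt(c(5, 6), c(0.5, 0.7), min_pairs = 1L)
  expect_true(est3$is_fallback)
})

test_that("estimate_ptt is invariant to a common time shift", {
  set.seed(7)
  r <- sort(runif(30, 0, 50))
  ppg <- r + runif(30, 0.15, 0.25)
  a <- estimate_ptt(r, ppg)
  b <- estimate_ptt(r + 4.321, ppg + 4.321)
  expect_equal(a$value, b$value)
  expect_equal(a$n_pairs, b$n_pairs)
})

test_that("perceivable_beats shifts beats by the transit time", {
  r <- event_series(c(10, 11), "r_wave")
  expect_equal(perceivable_beats(r, 0.2)$times, c(10.2, 11.2))
  expect_equal(length(perceivable_beats(event_series(numeric(0), "r_wave"),
                                        0.3)), 0L)
  # fallback estimate shifts by exactly 200 ms
  fb <- estimate_ptt(c(1, 2), numeric(0))
  expect_equal(perceivable_beats(r, fb)$times, c(10.2, 11.2))
  # beats shifted past the trial end are retained
  late <- event_series(c(59.9), "r_wave")
  expect_equal(perceivable_beats(late, 0.3)$times, 60.2)
})

test_that("perceivable-beat shifts are additive", {
  set.seed(11)
  r <- event_series(sort(runif(50, 0, 59)), "r_wave")
  twice <- perceivable_beats(perceivable_beats(r, 0.12), 0.08)
  once <- perceivable_beats(r, 0.20)
  expect_equal(twice$times, once$times)
})

test_that("beats_in_trial counts on the closed window", {
  expect_equal(beats_in_trial(regular_beats(66)), 66L)
  expect_equal(beats_in_trial(event_series(numeric(0), "r_wave")), 0L)
  # an event exactly at the window end is counted
  expect_equal(beats_in_trial(event_series(c(30, 60), "r_wave")), 2L)
  # counting respects an explicit window shorter than the series window
  es <- event_series(c(1, 2, 3), "r_wave", duration = 80)
  expect_equal(beats_in_trial(es, duration = 2.5), 2L)
})
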