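test_that("noise-free RR trains are evenly spaced at the requested rate", {
  r <- simulate_rr_train(mean_hr = 66, sdnn = 0, rsa_amp = 0, seed = 1)
  expect_true(length(r) %in% c(66L, 67L))
  expect_equal(unique(round(diff(r$times), 9)), 60 / 66)
  expect_error(simulate_rr_train(mean_hr = 20), "physiological")
})

test_that("stochastic RR trains hit the requested rate and variability", {
  counts <- vapply(1:300, function(i) {
    length(simulate_rr_train(mean_hr = 70, sdnn = 0.04, rsa_amp = 0,
                             seed = i))
  }, numeric(1L))
  expect_lt(abs(mean(counts) - 70), 1)
  rr_sd <- vapply(1:300, function(i) {
    sd(diff(simulate_rr_train(mean_hr = 70, sdnn = 0.04, rsa_amp = 0,
                              seed = 1000 + i)$times))
  }, numeric(1L))
  expect_lt(abs(mean(rr_sd) - 0.04) / 0.04, 0.1)
})

test_that("PPG trains are R waves delayed by the transit time", {
  r <- simulate_rr_train(mean_hr = 66, seed = 2)
  ppg <- simulate_ppg_train(r, ptt = 0.23, jitter = 0, seed = 3)
  expected <- r$times + 0.23
  expect_equal(ppg$times, expected[expected <= 60])  # recording ends at 60 s
  expect_false(estimate_ptt(r, ppg)$is_fallback)
  expect_equal(estimate_ptt(r, ppg)$value, 0.23)
  # median is robust to 5 ms arrival jitter
  ppg2 <- simulate_ppg_train(r, ptt = 0.20, jitter = 0.005, seed = 4)
  expect_lt(abs(estimate_ptt(r, ppg2)$value - 0.20), 0.005)
  empty <- simulate_ppg_train(event_series(numeric(0), "r_wave"), 0.2)
  expect_equal(length(empty), 0L)
})

test_that("tone schedules satisfy the design constants", {
  counts <- vapply(1:400, function(i) {
    length(simulate_tone_schedule(seed = i))
  }, numeric(1L))
  expect_true(all(counts >= 72 & counts <= 88))  # +/- 10% jitter bound
  expect_lt(abs(mean(counts) - 80), 0.75)        # 3 x MC standard error
  s <- simulate_tone_schedule(seed = 5)
  expect_false(is.unsorted(s$times, strictly = TRUE))
  expect_true(all(s$times >= 0 & s$times < 60))
})

test_that("tone rate modulation is 13 cycles per minute", {
  schedules <- lapply(1:200, function(i) simulate_tone_schedule(seed = i))
  f <- tone_modulation_frequency(schedules)
  expect_lt(abs(f - 13), 0.5)
})

test_that("deterministic tappers tap each beat at a fixed lag", {
  beats <- perceivable_beats(simulate_rr_train(mean_hr = 66, seed = 6), 0.2)
  prof <- perceptual_profile(p_detect = 1, delay_mu = 0.2, delay_sd = 0,
                             spurious_rate = 0)
  taps <- simulate_taps(beats, prof, "no_guessing", seed = 7)
  kept <- beats$times + 0.2
  expect_equal(taps$times, kept[kept <= 60])
  z <- beat_to_tap_consistency(taps, beats, seed = 8)$z
  expect_gt(z, 3)
})

test_that("non-detectors produce no evoked taps", {
  beats <- perceivable_beats(simulate_rr_train(mean_hr = 66, seed = 9), 0.2)
  prof <- perceptual_profile(p_detect = 0, spurious_rate = 0)
  taps <- simulate_taps(beats, prof, "no_guessing", seed = 10)
  expect_equal(length(taps), 0L)
  res <- beat_to_tap_consistency(taps, beats, seed = 11)
  expect_false(res$valid)
})

test_that("spurious-only tapping matches the null's uniform law", {
  beats <- regular_beats(68)
  prof <- perceptual_profile(p_detect = 0, spurious_rate = 0.6)
  pooled <- unlist(lapply(1:300, function(i) {
    taps <- simulate_taps(beats, prof, "guessing", seed = 300 + i)
    assign_nearest(taps, beats)$delta
  }))
  set.seed(12)
  null_deltas <- assign_nearest(runif(length(pooled), 0, 60), beats)$delta
  ks <- suppressWarnings(stats::ks.test(pooled, null_deltas))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort generation is deterministic and order-independent", {
  co <- simulate_cohort(c(healthy = 10), master_seed = 31)
  expect_length(co$records, 40L)  # 10 subjects x 4 conditions
  expect_equal(nrow(co$metadata), 10L)
  co2 <- simulate_cohort(c(healthy = 10), master_seed = 31)
  f1 <- tempfile(); f2 <- tempfile()
  write_event_table(co$records, f1)
  write_event_table(co2$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  # permuting group creation order leaves each subject's events unchanged
  ab <- simulate_cohort(c(healthy = 2, dep_anx = 2), master_seed = 32)
  ba <- simulate_cohort(c(dep_anx = 2, healthy = 2), master_seed = 32)
  key <- function(co) {
    ord <- order(vapply(co$records, function(r) {
      paste(r$subject_id, r$condition)
    }, character(1L)))
    lapply(co$records[ord], function(r) r$streams$tap$times)
  }
  expect_identical(key(ab), key(ba))
  expect_error(simulate_cohort(c(unknown_group = 3), master_seed = 1),
               "template")
})

test_that("calibrated templates expose their target slope", {
  tpl <- ima_template(0.3)
  expect_s3_class(tpl, "group_template")
  expect_equal(tpl$target_ima, 0.3)
  expect_error(ima_template(0.5), "calibrated")
  # healthy default: detection rises, timing noise falls across trials 1-3
  h <- default_templates()$healthy$profile
  p <- vapply(c("guessing", "no_guessing", "breath_hold"), function(cond) {
    beattap:::profile_for_condition(h, cond)$p_detect
  }, numeric(1L))
  s <- vapply(c("guessing", "no_guessing", "breath_hold"), function(cond) {
    beattap:::profile_for_condition(h, cond)$delay_sd
  }, numeric(1L))
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(s[2:3]) < 0))
})
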