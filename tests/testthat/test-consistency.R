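test_that("assign_nearest picks the closest event with signed deltas", {
  a <- assign_nearest(c(1.1), c(1.0, 2.0))
  expect_equal(a$event_index, 1L)
  expect_equal(a$delta, 0.1)
  # preemptive tap: negative delta to the following event
  b <- assign_nearest(c(1.9), c(1.0, 2.0))
  expect_equal(b$event_index, 2L)
  expect_equal(b$delta, -0.1)
  # exact midpoint tie breaks toward the earlier event
  tie <- assign_nearest(c(1.5), c(1.0, 2.0))
  expect_equal(tie$event_index, 1L)
  expect_equal(tie$delta, 0.5)
  # taps outside the event span attach to the terminal events
  edge <- assign_nearest(c(0.2, 9.0), c(1.0, 2.0))
  expect_equal(edge$event_index, c(1L, 2L))
  expect_equal(edge$delta, c(-0.8, 7.0))
  expect_error(assign_nearest(c(1), numeric(0)), "empty")
})

test_that("assign_nearest matches the exhaustive all-pairs oracle", {
  set.seed(101)
  for (i in 1:200) {
    n_ev <- sample(2:60, 1L)
    events <- sort(runif(n_ev, 0, 60))
    taps <- runif(sample(2:40, 1L), 0, 60)
    got <- assign_nearest(taps, events)$event_index
    expect_identical(got, brute_force_nearest(taps, events))
  }
})

test_that("observed_delta_sd is the n-1 sample SD of signed deltas", {
  expect_equal(observed_delta_sd(c(0.1, 0.1, 0.1)), 0)
  expect_equal(observed_delta_sd(c(0.0, 0.2)), sqrt(0.02))
  expect_error(observed_delta_sd(c(0.1)), "2 tap assignments")
  a <- assign_nearest(c(1.0, 1.2), c(1.0, 2.0))
  expect_equal(observed_delta_sd(a), sd(c(0, 0.2)))
})

test_that("simulate_null is reproducible and defaults to 1000 replicates", {
  ev <- regular_beats(70)$times
  n1 <- simulate_null(ev, n_taps = 30)
  expect_equal(n1$n_sims, 1000L)
  a <- simulate_null(ev, 30, seed = 5)
  b <- simulate_null(ev, 30, seed = 5)
  expect_identical(a$mean_sd, b$mean_sd)
  expect_identical(a$sd_sd, b$sd_sd)
  expect_gt(a$sd_sd, 0)
  expect_error(simulate_null(ev, n_taps = 1), ">= 2")
  expect_error(simulate_null(c(1), n_taps = 10), ">= 2")
})

test_that("null moments agree across seeds within Monte-Carlo error", {
  ev <- regular_beats(70)$times
  a <- simulate_null(ev, 30, n_sims = 1000, seed = 1)
  b <- simulate_null(ev, 30, n_sims = 1000, seed = 2)
  mc_se <- a$sd_sd / sqrt(1000)
  expect_lt(abs(a$mean_sd - b$mean_sd), 3 * sqrt(2) * mc_se)
})

test_that("the consistency z-score follows its definition and sign", {
  ev <- regular_beats(64)$times
  set.seed(3)
  taps <- sort(runif(25, 0, 60))
  res <- beat_to_tap_consistency(taps, ev, seed = 9)
  expect_true(res$valid)
  expect_equal(res$z,
               (res$null$mean_sd - res$observed_sd) / res$null$sd_sd)
  # taps phase-locked to jittered beats: far more consistent than chance
  set.seed(4)
  rr <- 0.9 + rnorm(66, 0, 0.05)
  beats <- cumsum(rr)
  beats <- beats[beats <= 60]
  locked <- beats[seq(1, length(beats), by = 2)] + 0.25
  z_locked <- beat_to_tap_consistency(locked, beats, seed = 10)$z
  expect_gt(z_locked, 3)
})

test_that("trials with too few taps or events are flagged, not errors", {
  ev <- regular_beats(66)$times
  res <- beat_to_tap_consistency(c(5), ev, seed = 1)
  expect_false(res$valid)
  expect_true(is.na(res$z))
  expect_equal(res$n_taps, 1L)
  res2 <- beat_to_tap_consistency(c(5, 6, 7), c(30), seed = 1)
  expect_false(res2$valid)
  res3 <- beat_to_tap_consistency(numeric(0), ev, seed = 1)
  expect_false(res3$valid)
})

test_that("z is non-increasing in tap-timing jitter down to its floor", {
  sig_grid <- c(0, 0.02, 0.05, 0.1, 0.2, 0.4)
  n_subj <- 200
  mean_z <- vapply(seq_along(sig_grid), function(gi) {
    zs <- vapply(seq_len(n_subj), function(i) {
      seed <- 5000L + gi * 1000L + i
      set.seed(seed)
      rr <- 0.9 + rnorm(80, 0, 0.05)
      beats <- cumsum(rr)
      beats <- beats[beats <= 60]
      taps <- sort(beats + 0.2 + rnorm(length(beats), 0, sig_grid[gi]))
      taps <- taps[taps >= 0 & taps <= 60]
      beat_to_tap_consistency(taps, beats, n_sims = 300, seed = seed)$z
    }, numeric(1L))
    mean(zs)
  }, numeric(1L))
  # strictly decreasing until the chance floor near 0
  expect_true(all(diff(mean_z[1:5]) < 0))
  expect_lt(mean_z[6], 0.5)
})

test_that("consistency results serialise to JSON", {
  ev <- regular_beats(66)$times
  res <- beat_to_tap_consistency(sort(runif(20, 0, 60)), ev, seed = 2)
  js <- jsonlite::fromJSON(consistency_to_json(res))
  expect_equal(js$z, res$z)
  expect_equal(js$n_sims, 1000L)
  expect_true(js$valid)
})
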