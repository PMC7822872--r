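#' Assign each tap to its nearest event
#'
#' Each tap is assigned to the heartbeat (or tone) event minimising the
#' absolute time difference, and receives a signed delta
#' `tap_time - event_time` (positive when the tap follows its event). The
#' nearest-event rule, rather than previous-event, accommodates preemptive
#' responses to anticipated events. Exact midpoint ties break toward the
#' earlier event; taps before the first or after the last event attach to
#' that terminal event.
#'
#' @param taps [event_series()] (or numeric vector) of tap times.
#' @param events [event_series()] (or numeric vector) of event times,
#'   sorted increasing, non-empty.
#' @return Data frame with columns `tap_time`, `event_index` (1-based into
#'   `events`), and `delta` (signed seconds).
#' @examples
#' assign_nearest(c(1.1, 1.5), c(1, 2))
#' @export
assign_nearest <- function(taps, events) {
  tp <- event_times(taps)
  ev <- event_times(events)
  if (!length(ev)) {
    stop("cannot assign taps: event series is empty", call. = FALSE)
  }
  idx <- nearest_event_index(tp, ev)
  data.frame(tap_time = tp, event_index = idx, delta = tp - ev[idx])
}

# Vectorised nearest-neighbour lookup into a sorted event vector.
# Ties at exact midpoints go to the earlier event.
nearest_event_index <- function(x, ev) {
  n <- length(ev)
  i <- findInterval(x, ev)
  i0 <- pmax(i, 1L)                     # candidate on/left
  i1 <- pmin(i + 1L, n)                 # candidate right
  take_left <- (i >= 1L) & (i == n | (x - ev[i0]) <= (ev[i1] - x))
  out <- i1
  out[take_left] <- i0[take_left]
  out
}

#' Standard deviation of signed tap deltas
#'
#' The raw (uncorrected) tapping-variability measure: the sample standard
#' deviation (denominator n - 1) of the signed tap-to-nearest-event time
#' differences. Trials with fewer than two taps carry no variability
#' information and are an error here; the pipeline records them as
#' exclusions instead.
#'
#' @param assignments Result of [assign_nearest()], or a numeric vector of
#'   signed deltas.
#' @return Standard deviation in seconds.
#' @export
observed_delta_sd <- function(assignments) {
  d <- if (is.data.frame(assignments)) assignments$delta else as.numeric(assignments)
  if (length(d) < 2L) {
    stop("at least 2 tap assignments are required to compute a delta SD",
         call. = FALSE)
  }
  stats::sd(d)
}

#' Monte-Carlo null distribution under uniformly random tapping
#'
#' Estimates the distribution of the delta SD expected if the participant
#' had tapped at random: for each replicate, `n_taps` taps are drawn i.i.d.
#' Uniform\[0, duration\] and scored against the participant's *actual*
#' event train with [assign_nearest()] + [observed_delta_sd()]. Because
#' faster heart rates shorten the window around each beat, the raw delta SD
#' shrinks with heart rate even for random tapping; this null captures that
#' dependence so it can be divided out.
#'
#' @param events [event_series()] (or numeric vector) of the trial's real
#'   event times (perceivable beats or tones); at least 2 events.
#' @param n_taps Number of taps the participant actually made (>= 2).
#' @param duration Trial window in seconds (default 60).
#' @param n_sims Number of simulated trials (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `null_distribution`: list with `n_sims`,
#'   `mean_sd`, `sd_sd` (mean and n-1 SD of the replicate delta SDs, in
#'   seconds), and `seed`.
#' @export
simulate_null <- function(events, n_taps, duration = 60, n_sims = 1000,
                          seed = NULL) {
  ev <- event_times(events)
  if (length(ev) < 2L || n_taps < 2L || n_sims < 2L) {
    stop("null simulation requires >= 2 events, >= 2 taps and >= 2 replicates",
         call. = FALSE)
  }
  sds <- with_seed(seed, {
    taps <- stats::runif(as.numeric(n_taps) * n_sims, 0, duration)
    idx <- nearest_event_index(taps, ev)
    dm <- matrix(taps - ev[idx], nrow = n_taps)
    m <- colMeans(dm)
    sqrt(pmax(colSums(dm * dm) - n_taps * m * m, 0) / (n_taps - 1))
  })
  structure(list(n_sims = as.integer(n_sims), mean_sd = mean(sds),
                 sd_sd = stats::sd(sds),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> mean_sd=%.4f s sd_sd=%.4f s (n_sims=%d)\n",
              x$mean_sd, x$sd_sd, x$n_sims))
  invisible(x)
}

#' Beat-to-tap consistency: heart-rate-corrected tapping precision
#'
#' The core perceptual statistic. The observed SD of signed
#' tap-to-nearest-event deltas is converted to a Z-score against the
#' Monte-Carlo null of uniformly random tapping on the same event train
#' ([simulate_null()]):
#' \deqn{z = (\mathrm{mean}_{null} - SD_{obs}) / \mathrm{sd}_{null}}
#' so that larger z means tapping more temporally consistent than chance.
#' By construction z is corrected for — and uncorrelated with — the
#' participant's actual heart rate and number of taps. Trials with fewer
#' than 2 taps or fewer than 2 events cannot be scored and are returned
#' with `valid = FALSE` (never an error), so a cohort pipeline can tally
#' exclusions.
#'
#' @param taps [event_series()] (or numeric vector) of tap times.
#' @param events [event_series()] (or numeric vector) of perceivable-beat
#'   or tone times.
#' @param duration Trial window in seconds (default 60).
#' @param n_sims Monte-Carlo replicates for the null (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `consistency_result`: list with
#'   `observed_sd`, `z`, `n_taps`, `n_events`, `valid`, and `null`
#'   (the [simulate_null()] result, `NULL` when invalid).
#' @examples
#' beats <- seq(0.5, 59.5, by = 0.9)
#' taps <- beats[seq(1, length(beats), by = 2)] + 0.25
#' res <- beat_to_tap_consistency(taps, beats, seed = 1)
#' res$z > 3
#' @export
beat_to_tap_consistency <- function(taps, events, duration = 60,
                                    n_sims = 1000, seed = NULL) {
  tp <- event_times(taps)
  ev <- event_times(events)
  if (length(tp) < 2L || length(ev) < 2L) {
    return(structure(list(observed_sd = NA_real_, z = NA_real_,
                          n_taps = length(tp), n_events = length(ev),
                          valid = FALSE, null = NULL),
                     class = "consistency_result"))
  }
  obs <- observed_delta_sd(assign_nearest(tp, ev))
  null <- simulate_null(ev, n_taps = length(tp), duration = duration,
                        n_sims = n_sims, seed = seed)
  structure(list(observed_sd = obs,
                 z = (null$mean_sd - obs) / null$sd_sd,
                 n_taps = length(tp), n_events = length(ev),
                 valid = TRUE, null = null),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<consistency_result> invalid (n_taps=%d, n_events=%d)\n",
                x$n_taps, x$n_events))
  } else {
    cat(sprintf("<consistency_result> z=%.3f observed_sd=%.4f s (taps=%d, events=%d)\n",
                x$z, x$observed_sd, x$n_taps, x$n_events))
  }
  invisible(x)
}

#' Serialise a consistency result to JSON
#'
#' @param x A `consistency_result`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
consistency_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "consistency_result"))
  obj <- list(observed_sd = x$observed_sd, z = x$z, n_taps = x$n_taps,
              n_events = x$n_events,
              n_sims = if (is.null(x$null)) NA_integer_ else x$null$n_sims,
              seed = if (is.null(x$null)) NA_integer_ else x$null$seed,
              valid = x$valid)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
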