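#' Estimate pulse transit time from paired R-wave and pulse-wave events
#'
#' Pulse transit time (PTT) is the delay between the ECG R wave and the
#' arrival of the pulse wave at the recording site (here, the positive
#' inflection / foot of an earlobe PPG signal). Each pulse-wave event is
#' matched to the nearest preceding R wave with a delay in `(0, max_lag]`;
#' unmatched pulse events are dropped. The estimate is the median of the
#' matched delays. When fewer than `min_pairs` delays can be matched the
#' estimator falls back to 0.200 s, a standard value for the ear site.
#'
#' @param r_times [event_series()] (or numeric vector) of R-wave times.
#' @param ppg_times [event_series()] (or numeric vector) of pulse-wave
#'   (PPG foot) times from the same trial.
#' @param max_lag Largest physiologically admissible R-to-pulse delay in
#'   seconds (default 1.0, well above any ear PTT).
#' @param min_pairs Minimum number of matched pairs for a data-driven
#'   estimate (default 5); below this the 0.200-s fallback is returned,
#'   since a median of very few beats is unstable.
#' @return An object of class `ptt_estimate`: list with `value` (seconds),
#'   `n_pairs`, and `is_fallback`.
#' @examples
#' r <- event_series(1:6, "r_wave", duration = 10)
#' p <- event_series(1:6 + 0.21, "ppg_foot", duration = 10)
#' estimate_ptt(r, p)$value
#' @export
estimate_ptt <- function(r_times, ppg_times, max_lag = 1.0, min_pairs = 5L) {
  r <- event_times(r_times)
  p <- event_times(ppg_times)
  delays <- numeric(0)
  if (length(r) && length(p)) {
    i <- findInterval(p, r)        # index of last R at or before each pulse
    ok <- i >= 1L
    d <- p[ok] - r[i[ok]]
    delays <- d[d > 0 & d <= max_lag]
  }
  if (length(delays) < min_pairs) {
    return(structure(list(value = 0.200, n_pairs = length(delays),
                          is_fallback = TRUE), class = "ptt_estimate"))
  }
  structure(list(value = stats::median(delays), n_pairs = length(delays),
                 is_fallback = FALSE), class = "ptt_estimate")
}

#' @export
print.ptt_estimate <- function(x, ...) {
  cat(sprintf("<ptt_estimate> %.3f s (%d pairs%s)\n", x$value, x$n_pairs,
              if (x$is_fallback) ", fallback" else ""))
  invisible(x)
}

#' Perceivable beats: systole onsets placed by pulse transit time
#'
#' The sensation of a heartbeat is available no earlier than the arrival of
#' the pressure wave, so potentially perceivable beats are placed at the
#' onset of systole: each R-wave time shifted forward by the pulse transit
#' time. Beats shifted past the nominal trial end are retained and the
#' series window is extended to cover them.
#'
#' @param r_times [event_series()] (or numeric vector) of R-wave times.
#' @param ptt A [estimate_ptt()] result, or a single numeric shift in
#'   seconds.
#' @return An `event_series` with stream `"r_wave"` shifted by the PTT.
#' @export
perceivable_beats <- function(r_times, ptt) {
  shift <- if (inherits(ptt, "ptt_estimate")) ptt$value else as.numeric(ptt)
  if (length(shift) != 1L || is.na(shift)) {
    stop("ptt must be a single numeric shift or a ptt_estimate", call. = FALSE)
  }
  t <- event_times(r_times) + shift
  dur <- if (inherits(r_times, "event_series")) r_times$duration else 60
  event_series(t, stream = "r_wave",
               duration = max(dur, if (length(t)) t[length(t)] else 0))
}

#' Count heartbeats recorded within the trial window
#'
#' Number of R-wave events with time on the closed interval
#' `[0, duration]`.
#'
#' @param r_times [event_series()] of R-wave times, or numeric vector.
#' @param duration Trial window in seconds; defaults to the series' own
#'   duration (or 60 for a bare vector).
#' @return Integer count.
#' @export
beats_in_trial <- function(r_times, duration = NULL) {
  if (is.null(duration)) {
    duration <- if (inherits(r_times, "event_series")) r_times$duration else 60
  }
  t <- event_times(r_times)
  sum(t >= 0 & t <= duration)
}
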