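#' Counting accuracy adapted to the tapping task
#'
#' The standard heartbeat-counting accuracy formula with the reported count
#' replaced by the number of taps:
#' \deqn{1 - |n_{beats} - n_{taps}| / n_{beats}}
#' clipped below at 0 so the score stays a proportion. 1 means the tap
#' count matched the recorded beat count exactly; 0 means the discrepancy
#' was at least as large as the beat count itself. The measure is
#' scale-free: (70 beats, 35 taps) scores the same as (140, 70).
#'
#' @param n_beats Number of recorded heartbeats (>= 1).
#' @param n_taps Number of taps.
#' @return Accuracy in `[0, 1]`; vectorised over both arguments.
#' @examples
#' counting_accuracy(70, 35)
#' @export
counting_accuracy <- function(n_beats, n_taps) {
  if (any(n_beats < 1)) {
    stop("counting accuracy is undefined for n_beats < 1", call. = FALSE)
  }
  pmax(0, 1 - abs(n_beats - n_taps) / n_beats)
}

#' Mean signed tap delay
#'
#' Arithmetic mean of the signed tap-to-nearest-event deltas: positive when
#' taps tend to follow their events. Unlike the consistency statistic this
#' reflects reaction-time offsets, which is why it is reported separately.
#'
#' @param assignments Result of [assign_nearest()], or numeric deltas.
#' @return Mean delay in seconds.
#' @export
mean_delay <- function(assignments) {
  d <- if (is.data.frame(assignments)) assignments$delta else as.numeric(assignments)
  if (length(d) < 1L) {
    stop("mean delay is undefined with no tap assignments", call. = FALSE)
  }
  mean(d)
}
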