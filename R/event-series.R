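#' Event series: ordered event times within a trial window
#'
#' An `event_series` holds the onset times (seconds) of one event stream —
#' R waves, pulse-wave (PPG) feet, taps, or tones — within a single trial
#' window. Times must be strictly increasing and lie in `[0, duration]`.
#' An empty series is permitted and still carries its stream and duration.
#'
#' @param times Numeric vector of event times in seconds, strictly
#'   increasing, each in `[0, duration]`.
#' @param stream One of `"r_wave"`, `"ppg_foot"`, `"tap"`, `"tone"`.
#' @param duration Trial window length in seconds (default 60).
#' @return An object of class `event_series`: a list with elements
#'   `stream`, `times` and `duration`.
#' @examples
#' es <- event_series(c(0.8, 1.7, 2.6), "r_wave")
#' length(es$times)
#' @export
event_series <- function(times, stream = c("r_wave", "ppg_foot", "tap", "tone"),
                         duration = 60) {
  stream <- match.arg(stream)
  times <- as.numeric(times)
  if (anyNA(times)) {
    stop("event times must not contain NA", call. = FALSE)
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("duration must be a single positive number", call. = FALSE)
  }
  if (length(times) > 0L) {
    if (is.unsorted(times, strictly = TRUE)) {
      stop("event times must be strictly increasing", call. = FALSE)
    }
    if (times[1L] < 0 || times[length(times)] > duration) {
      stop("event times must lie in [0, duration]", call. = FALSE)
    }
  }
  structure(list(stream = stream, times = times, duration = duration),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> stream=%s n=%d duration=%gs\n",
              x$stream, length(x$times), x$duration))
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$times)

# Accept either an event_series or a bare numeric vector of times.
event_times <- function(x) {
  if (inherits(x, "event_series")) x$times else as.numeric(x)
}

#' Trial record: one subject x condition
#'
#' Bundles the event streams recorded during one 60-s trial together with
#' the subject's identity, diagnostic group, task condition, and optional
#' self-report ratings. Heartbeat conditions (guessing, no-guessing,
#' breath-hold) must carry an `r_wave` stream; the tone control trial must
#' carry a `tone` stream. Trial index codes the heartbeat conditions
#' 1 (guessing), 2 (no guessing), 3 (no guessing + breath hold); the tone
#' trial has no index.
#'
#' @param subject_id Character scalar.
#' @param group One of `"healthy"`, `"dep_anx"`, `"sud"`.
#' @param condition One of `"guessing"`, `"no_guessing"`, `"breath_hold"`,
#'   `"tone"`.
#' @param streams Named list of [event_series()], keyed by stream name.
#' @param confidence,intensity,difficulty Optional self-report ratings on a
#'   0-100 visual-analogue scale.
#' @param duration Trial window in seconds (default 60).
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(subject_id, group, condition, streams,
                         confidence = NA_real_, intensity = NA_real_,
                         difficulty = NA_real_, duration = 60) {
  group <- match.arg(group, c("healthy", "dep_anx", "sud"))
  condition <- match.arg(condition,
                         c("guessing", "no_guessing", "breath_hold", "tone"))
  if (!is.list(streams)) {
    stop("streams must be a named list of event_series", call. = FALSE)
  }
  is_es <- vapply(streams, inherits, logical(1L), what = "event_series")
  if (length(streams) && !all(is_es)) {
    stop("all streams must be event_series objects", call. = FALSE)
  }
  names(streams) <- vapply(streams, `[[`, character(1L), "stream")
  if (condition == "tone" && is.null(streams$tone)) {
    stop("tone trials require a tone stream", call. = FALSE)
  }
  if (condition != "tone" && is.null(streams$r_wave)) {
    stop("heartbeat trials require an r_wave stream", call. = FALSE)
  }
  structure(list(
    subject_id = as.character(subject_id),
    group = group,
    condition = condition,
    trial_index = trial_index(condition),
    streams = streams,
    confidence = confidence,
    intensity = intensity,
    difficulty = difficulty,
    duration = duration
  ), class = "trial_record")
}

#' Trial index coding of the heartbeat conditions
#'
#' @param condition Condition label(s).
#' @return Integer 1, 2, 3 for guessing, no-guessing, breath-hold; `NA` for
#'   the tone trial.
#' @export
trial_index <- function(condition) {
  idx <- c(guessing = 1L, no_guessing = 2L, breath_hold = 3L, tone = NA_integer_)
  unname(idx[condition])
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s | %s | %s | streams: %s\n",
              x$subject_id, x$group, x$condition,
              paste(names(x$streams), collapse = ", ")))
  invisible(x)
}

#' Read an event table into trial records
#'
#' Reads a long-format CSV with columns `subject_id`, `group`, `condition`,
#' `stream`, `time_s` (one row per event) and assembles one [trial_record()]
#' per subject x condition. Rows with a non-numeric or out-of-window time
#' are rejected, collected, and reported as a warning listing their file
#' line numbers; they never silently disappear. Times are sorted within
#' each stream. Exact duplicate times within a stream are collapsed to one
#' event (reported alongside the malformed rows).
#'
#' @param path Path to the CSV file.
#' @param duration Trial window in seconds (default 60). Times outside
#'   `[0, duration]` are clipped out and reported.
#' @param metadata Optional path to a metadata CSV with columns
#'   `subject_id`, `group`, `age`, `sex`, `medicated` and per-condition
#'   `confidence`/`intensity`/`difficulty` columns named
#'   `<rating>_<condition>`. Ratings are attached to the matching trials.
#' @return A list of `trial_record` objects with attributes `rejected`
#'   (data frame of rejected rows with line numbers and reasons) and
#'   `metadata` (the metadata data frame, if supplied).
#' @export
read_event_table <- function(path, duration = 60, metadata = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("event table not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  required <- c("subject_id", "group", "condition", "stream", "time_s")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("event table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(raw)
  line_no <- seq_len(n) + 1L  # header is line 1
  time_s <- suppressWarnings(as.numeric(raw$time_s))
  bad_time <- is.na(time_s)
  out_of_window <- !bad_time & (time_s < 0 | time_s > duration)
  bad_label <- !(raw$stream %in% c("r_wave", "ppg_foot", "tap", "tone")) |
    !(raw$condition %in% c("guessing", "no_guessing", "breath_hold", "tone")) |
    !(raw$group %in% c("healthy", "dep_anx", "sud"))
  reject <- bad_time | out_of_window | bad_label
  reason <- character(n)
  reason[bad_label] <- "unrecognised stream/condition/group label"
  reason[out_of_window] <- "time outside [0, duration]"
  reason[bad_time] <- "non-numeric time_s"
  rejected <- data.frame(line = line_no[reject], reason = reason[reject],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s",
                    nrow(rejected),
                    paste(rejected$line, collapse = ", ")), call. = FALSE)
  }
  keep <- raw[!reject, , drop = FALSE]
  keep$time_s <- time_s[!reject]

  meta <- NULL
  if (!is.null(metadata)) {
    meta <- utils::read.csv(metadata, check.names = FALSE, strip.white = TRUE)
    if (!"subject_id" %in% names(meta)) {
      stop("metadata table is missing column subject_id", call. = FALSE)
    }
  }

  records <- list()
  if (nrow(keep)) {
    key <- interaction(keep$subject_id, keep$condition, drop = TRUE)
    for (grp in split(keep, key)) {
      streams <- lapply(split(grp, grp$stream), function(g) {
        event_series(sort(unique(g$time_s)), stream = g$stream[1L],
                     duration = duration)
      })
      ratings <- c(confidence = NA_real_, intensity = NA_real_,
                   difficulty = NA_real_)
      if (!is.null(meta)) {
        row <- meta[match(grp$subject_id[1L], meta$subject_id), , drop = FALSE]
        for (r in names(ratings)) {
          col <- paste0(r, "_", grp$condition[1L])
          if (col %in% names(row)) ratings[[r]] <- as.numeric(row[[col]])
        }
      }
      records[[length(records) + 1L]] <- trial_record(
        subject_id = grp$subject_id[1L],
        group = grp$group[1L],
        condition = grp$condition[1L],
        streams = unname(streams),
        confidence = ratings[["confidence"]],
        intensity = ratings[["intensity"]],
        difficulty = ratings[["difficulty"]],
        duration = duration
      )
    }
  }
  attr(records, "rejected") <- rejected
  attr(records, "metadata") <- meta
  records
}

#' Write trial records to an event table
#'
#' Inverse of [read_event_table()]: writes one row per event, in long
#' format, with times printed to microsecond precision.
#'
#' @param records List of [trial_record()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(records, path) {
  rows <- lapply(records, function(rec) {
    do.call(rbind, lapply(rec$streams, function(es) {
      if (!length(es$times)) return(NULL)
      data.frame(subject_id = rec$subject_id, group = rec$group,
                 condition = rec$condition, stream = es$stream,
                 time_s = sprintf("%.6f", es$times),
                 stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(subject_id = character(), group = character(),
                      condition = character(), stream = character(),
                      time_s = character())
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
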