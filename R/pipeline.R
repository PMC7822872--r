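#' Per-trial metrics for a cohort
#'
#' Scores every trial record: events are perceivable beats (R waves shifted
#' by the trial's estimated pulse transit time, [estimate_ptt()] with its
#' 200-ms fallback) for heartbeat conditions, and tone onsets for the tone
#' trial. Computes the beat-to-tap consistency z, raw delta SD, counting
#' accuracy, mean signed delay, and counts. Trials that cannot be scored
#' (fewer than 2 taps, fewer than 2 events, missing streams) appear in the
#' table with `valid = FALSE` and are tallied in the exclusion log, so
#' participant loss is always accounted for.
#'
#' @param cohort A [simulate_cohort()] result, or a bare list of
#'   [trial_record()] objects (e.g. from [read_event_table()]).
#' @param n_sims Monte-Carlo replicates per trial null (default 1000).
#' @param seed Integer master seed; per-trial nulls use sub-seeds derived
#'   from it, so results do not depend on record order.
#' @return A `cohort_table` data frame, one row per subject x condition,
#'   with attribute `exclusions` (data frame subject_id, condition,
#'   reason).
#' @export
compute_trial_metrics <- function(cohort, n_sims = 1000, seed = 1) {
  records <- if (inherits(cohort, "cohort")) cohort$records else cohort
  n <- length(records)
  col <- list(
    subject_id = character(n), group = character(n), condition = character(n),
    trial_index = rep(NA_integer_, n), z = rep(NA_real_, n),
    observed_sd = rep(NA_real_, n), n_taps = integer(n),
    n_beats = rep(NA_integer_, n), n_events = rep(NA_integer_, n),
    heart_rate = rep(NA_real_, n), counting_accuracy = rep(NA_real_, n),
    mean_delay = rep(NA_real_, n), confidence = rep(NA_real_, n),
    intensity = rep(NA_real_, n), difficulty = rep(NA_real_, n),
    valid = logical(n))
  ex_sid <- character(0); ex_cond <- character(0); ex_reason <- character(0)
  for (k in seq_len(n)) {
    rec <- records[[k]]
    dur <- rec$duration
    taps <- rec$streams$tap %||% event_series(numeric(0), "tap", dur)
    if (rec$condition == "tone") {
      events <- rec$streams$tone
      n_beats <- if (!is.null(rec$streams$r_wave)) {
        beats_in_trial(rec$streams$r_wave)
      } else NA_integer_
      n_targets <- length(events$times)
    } else {
      r <- rec$streams$r_wave
      ptt <- if (!is.null(rec$streams$ppg_foot)) {
        estimate_ptt(r, rec$streams$ppg_foot)
      } else {
        estimate_ptt(r, numeric(0))
      }
      events <- perceivable_beats(r, ptt)
      n_beats <- beats_in_trial(r)
      n_targets <- n_beats
    }
    trial_seed <- derive_seed(seed, k + 7919L * nchar(rec$subject_id))
    cr <- beat_to_tap_consistency(taps, events, duration = dur,
                                  n_sims = n_sims, seed = trial_seed)
    if (!cr$valid) {
      ex_sid <- c(ex_sid, rec$subject_id)
      ex_cond <- c(ex_cond, rec$condition)
      ex_reason <- c(ex_reason, if (cr$n_taps < 2L) "fewer than 2 taps"
                                else "fewer than 2 events")
    }
    tp <- taps$times
    ev <- events$times
    col$subject_id[k] <- rec$subject_id
    col$group[k] <- rec$group
    col$condition[k] <- rec$condition
    col$trial_index[k] <- rec$trial_index
    if (cr$valid) {
      col$z[k] <- cr$z
      col$observed_sd[k] <- cr$observed_sd
    }
    col$n_taps[k] <- length(tp)
    col$n_beats[k] <- n_beats
    col$n_events[k] <- n_targets
    if (!is.na(n_beats)) col$heart_rate[k] <- n_beats * 60 / dur
    if (!is.na(n_targets) && n_targets >= 1) {
      col$counting_accuracy[k] <- counting_accuracy(n_targets, length(tp))
    }
    if (length(tp) >= 1L && length(ev) >= 1L) {
      col$mean_delay[k] <- mean(tp - ev[nearest_event_index(tp, ev)])
    }
    col$confidence[k] <- rec$confidence
    col$intensity[k] <- rec$intensity
    col$difficulty[k] <- rec$difficulty
    col$valid[k] <- cr$valid
  }
  out <- as.data.frame(col, stringsAsFactors = FALSE)
  excl <- data.frame(subject_id = ex_sid, condition = ex_cond,
                     reason = ex_reason, stringsAsFactors = FALSE)
  attr(out, "exclusions") <- excl
  class(out) <- c("cohort_table", class(out))
  out
}

#' Per-subject interoceptive modulation ability (IMA) slopes
#'
#' Summarises each subject's change in beat-to-tap consistency across the
#' three heartbeat conditions (trial index 1, 2, 3) as the least-squares
#' slope of z on trial index — the interoceptive modulation ability. The
#' tone trial contributes the subject's tone-to-tap consistency (TTC),
#' optionally used to residualise z before slope fitting (removing
#' non-interoceptive response tendencies shared with the auditory task).
#' Subjects with fewer than 2 valid heartbeat conditions are marked
#' non-estimable. With `shrinkage = TRUE` the raw slopes are shrunk toward
#' the grand mean by reliability weights (a two-stage random-coefficient
#' approximation of a mixed model with random slopes): each slope gets
#' weight `tau2 / (tau2 + v_i)`, with `v_i` the sampling variance of the
#' subject's OLS slope from the pooled residual variance and `tau2` the
#' method-of-moments between-subject slope variance.
#'
#' @param table A `cohort_table` from [compute_trial_metrics()].
#' @param shrinkage Shrink slopes toward the grand mean (default FALSE).
#' @param ttc_adjust Residualise z on TTC (per observation, across
#'   subjects) before fitting slopes (default FALSE).
#' @return A `subject_summary` data frame: subject_id, group, ima_slope,
#'   intercept, n_conditions_used, ttc, excluded, reason. Attribute
#'   `method` records the estimator used.
#' @export
ima_slopes <- function(table, shrinkage = FALSE, ttc_adjust = FALSE) {
  hb <- table[!is.na(table$trial_index), , drop = FALSE]
  tone <- table[table$condition == "tone", , drop = FALSE]
  ttc_map <- stats::setNames(tone$z, tone$subject_id)
  hb$ttc <- unname(ttc_map[hb$subject_id])
  if (ttc_adjust) {
    use <- hb$valid & !is.na(hb$ttc)
    if (sum(use) >= 3L) {
      fit <- stats::lm(z ~ ttc, data = hb[use, ])
      hb$z[use] <- stats::residuals(fit) + mean(hb$z[use])
    }
  }
  subjects <- unique(table$subject_id)
  res <- lapply(subjects, function(sid) {
    rows <- hb[hb$subject_id == sid & hb$valid & !is.na(hb$z), , drop = FALSE]
    grp <- table$group[match(sid, table$subject_id)]
    ttc <- if (sid %in% names(ttc_map)) unname(ttc_map[[sid]]) else NA_real_
    if (nrow(rows) < 2L) {
      return(data.frame(subject_id = sid, group = grp, ima_slope = NA_real_,
                        intercept = NA_real_, rss = NA_real_,
                        resid_df = 0L, sxx = NA_real_,
                        n_conditions_used = nrow(rows), ttc = ttc,
                        excluded = TRUE, reason = "non-estimable slope",
                        stringsAsFactors = FALSE))
    }
    x <- rows$trial_index
    y <- rows$z
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    rss <- sum((y - mean(y) - slope * (x - mean(x)))^2)
    data.frame(subject_id = sid, group = grp, ima_slope = slope,
               intercept = mean(y) - slope * mean(x),
               rss = rss, resid_df = nrow(rows) - 2L, sxx = sxx,
               n_conditions_used = nrow(rows), ttc = ttc, excluded = FALSE,
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  method <- "per-subject OLS"
  if (shrinkage) {
    est <- !out$excluded
    # pooled residual variance: per-subject 1-df variances are too unstable
    df_tot <- sum(out$resid_df[est])
    sigma2 <- if (df_tot > 0) sum(out$rss[est]) / df_tot else 0
    v <- sigma2 / out$sxx[est]
    tau2 <- max(0, stats::var(out$ima_slope[est]) - mean(v))
    w <- tau2 / (tau2 + v)
    gm <- mean(out$ima_slope[est])
    out$ima_slope[est] <- gm + w * (out$ima_slope[est] - gm)
    method <- "two-stage random-coefficient shrinkage"
  }
  if (ttc_adjust) method <- paste(method, "+ TTC residualisation")
  out$rss <- NULL
  out$resid_df <- NULL
  out$sxx <- NULL
  attr(out, "method") <- method
  class(out) <- c("subject_summary", class(out))
  out
}

#' Group contrast of IMA slopes by label permutation
#'
#' Tests whether mean interoceptive modulation ability differs between
#' groups — the group-by-condition interaction — without distributional
#' assumptions. For two groups the statistic is the absolute difference in
#' group mean slopes; for three or more it is the one-way F ratio on
#' slopes. The null distribution is obtained by permuting group labels
#' across subjects; the p-value is `(1 + #{perm >= obs}) / (n_perms + 1)`,
#' floored at `1/(n_perms + 1)`.
#'
#' @param summaries A `subject_summary` from [ima_slopes()].
#' @param groups Character vector of groups to compare (default: all groups
#'   present with estimable slopes).
#' @param n_perms Number of label permutations (default 10000).
#' @param seed Optional integer seed.
#' @return An object of class `contrast_result`: list with `statistic`,
#'   `perm_p`, `n_perms`, `seed`, `groups`, and `group_means` (data frame
#'   with per-group mean slope, SE, and normal-theory 95% CI).
#' @export
group_condition_contrast <- function(summaries, groups = NULL,
                                     n_perms = 10000, seed = NULL) {
  ok <- !summaries$excluded & !is.na(summaries$ima_slope)
  dat <- summaries[ok, , drop = FALSE]
  groups <- groups %||% sort(unique(dat$group))
  dat <- dat[dat$group %in% groups, , drop = FALSE]
  counts <- table(factor(dat$group, levels = groups))
  if (length(groups) < 2L || any(counts < 2L)) {
    stop("contrast requires >= 2 groups with >= 2 estimable slopes each",
         call. = FALSE)
  }
  slopes <- dat$ima_slope
  labels <- factor(dat$group, levels = groups)
  stat_fun <- if (length(groups) == 2L) {
    function(y, g) abs(mean(y[g == groups[1L]]) - mean(y[g == groups[2L]]))
  } else {
    function(y, g) {
      m <- tapply(y, g, mean)
      n <- tapply(y, g, length)
      ssb <- sum(n * (m - mean(y))^2)
      ssw <- sum((y - m[g])^2)
      (ssb / (length(groups) - 1L)) / (ssw / (length(y) - length(groups)))
    }
  }
  obs <- stat_fun(slopes, labels)
  perm <- with_seed(seed, vapply(seq_len(n_perms), function(i) {
    stat_fun(slopes, sample(labels))
  }, numeric(1L)))
  gm <- do.call(rbind, lapply(groups, function(g) {
    y <- slopes[labels == g]
    se <- stats::sd(y) / sqrt(length(y))
    data.frame(group = g, n = length(y), mean_slope = mean(y), se = se,
               ci_lo = mean(y) - 1.96 * se, ci_hi = mean(y) + 1.96 * se,
               stringsAsFactors = FALSE)
  }))
  structure(list(statistic = obs,
                 perm_p = (1 + sum(perm >= obs)) / (n_perms + 1),
                 n_perms = as.integer(n_perms),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 groups = groups, group_means = gm),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %s: statistic=%.4f perm_p=%.4g (n_perms=%d)\n",
              paste(x$groups, collapse = " vs "), x$statistic, x$perm_p,
              x$n_perms))
  print(x$group_means, row.names = FALSE)
  invisible(x)
}

#' Breath-hold manipulation check
#'
#' Paired comparison of the breath-hold condition against the no-guessing
#' condition within subjects, for the measures the manipulation should
#' move: number of taps, heart rate (beats), and the self-reported
#' confidence, intensity and difficulty ratings. Returns the paired mean
#' difference (breath hold minus no guessing) and paired t statistic per
#' measure.
#'
#' @param table A `cohort_table` from [compute_trial_metrics()].
#' @return Data frame: measure, n_pairs, mean_diff, t, df, p.
#' @export
breath_hold_check <- function(table) {
  a <- table[table$condition == "no_guessing", , drop = FALSE]
  b <- table[table$condition == "breath_hold", , drop = FALSE]
  common <- intersect(a$subject_id, b$subject_id)
  if (length(common) < 2L) {
    stop("breath-hold check requires >= 2 subjects with both conditions",
         call. = FALSE)
  }
  a <- a[match(common, a$subject_id), ]
  b <- b[match(common, b$subject_id), ]
  measures <- c("n_taps", "heart_rate", "confidence", "intensity",
                "difficulty")
  do.call(rbind, lapply(measures, function(m) {
    d <- b[[m]] - a[[m]]
    d <- d[!is.na(d)]
    if (length(d) < 2L || stats::sd(d) == 0) {
      return(data.frame(measure = m, n_pairs = length(d),
                        mean_diff = mean(d), t = NA_real_, df = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(d)
    data.frame(measure = m, n_pairs = length(d), mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
}

#' Combine variable importance across learners
#'
#' Aggregates per-method variable-importance scores into a single ranking:
#' each method's scores are min-max scaled to `[0, 100]` across variables,
#' then averaged across methods with weights proportional to each method's
#' predictive performance. Invariant to any positive rescaling of a single
#' method's raw scores.
#'
#' @param vi Numeric matrix, methods in rows, variables in columns;
#'   non-negative.
#' @param performance Numeric vector of per-method performance weights,
#'   non-negative, not all zero.
#' @return Named numeric vector of combined importances in `[0, 100]`.
#' @export
aggregate_variable_importance <- function(vi, performance) {
  vi <- as.matrix(vi)
  if (any(vi < 0)) stop("variable importances must be non-negative",
                        call. = FALSE)
  if (length(performance) != nrow(vi)) {
    stop("one performance weight per method (row) is required", call. = FALSE)
  }
  if (any(performance < 0) || sum(performance) == 0) {
    stop("performance weights must be non-negative and not all zero",
         call. = FALSE)
  }
  scaled <- t(apply(vi, 1L, function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) rep(0, length(v)) else 100 * (v - min(v)) / rng
  }))
  w <- performance / sum(performance)
  out <- colSums(scaled * w)
  names(out) <- colnames(vi)
  out
}

#' Write analysis artifacts to a directory
#'
#' Writes the cohort metrics table (TSV), the exclusion log (TSV), the
#' condition-by-group mean table (TSV), the contrast result(s) (JSON), and
#' a provenance record (JSON: seeds, parameters, package version).
#'
#' @param metrics A `cohort_table` from [compute_trial_metrics()].
#' @param summaries Optional `subject_summary` from [ima_slopes()];
#'   written as a TSV when supplied.
#' @param contrasts Optional [group_condition_contrast()] result or named
#'   list of them.
#' @param out_dir Output directory (created if absent).
#' @param params Optional list of run parameters for the provenance record.
#' @return Invisibly, the character vector of files written.
#' @export
report <- function(metrics, summaries = NULL, contrasts = NULL,
                   out_dir, params = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory %s", out_dir),
                  call. = FALSE)
  }
  written <- character(0)
  wtsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
  }
  wtsv(as.data.frame(metrics), "cohort_metrics.tsv")
  wtsv(attr(metrics, "exclusions") %||%
         data.frame(subject_id = character(), condition = character(),
                    reason = character()), "exclusions.tsv")
  valid <- metrics[metrics$valid %in% TRUE, , drop = FALSE]
  if (nrow(valid)) {
    means <- stats::aggregate(z ~ group + condition, data = valid, FUN = mean)
    ns <- stats::aggregate(z ~ group + condition, data = valid, FUN = length)
    names(ns)[3] <- "n"
    names(means)[3] <- "mean_z"
    wtsv(merge(means, ns), "group_condition_means.tsv")
  } else {
    wtsv(data.frame(group = character(), condition = character(),
                    mean_z = numeric(), n = integer()),
         "group_condition_means.tsv")
    warning("no valid trials: wrote empty summary tables", call. = FALSE)
  }
  if (!is.null(summaries)) wtsv(as.data.frame(summaries), "ima_slopes.tsv")
  if (!is.null(contrasts)) {
    if (inherits(contrasts, "contrast_result")) {
      contrasts <- list(contrast = contrasts)
    }
    path <- file.path(out_dir, "contrasts.json")
    jsonlite::write_json(lapply(contrasts, unclass), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
    written <- c(written, path)
  }
  prov <- c(list(package = "beattap",
                 version = as.character(utils::packageVersion("beattap")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 n_trials = nrow(metrics)), params)
  path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  written <- c(written, path)
  invisible(written)
}
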