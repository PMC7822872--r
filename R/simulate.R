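#' Simulate an R-wave train with beat-to-beat variability
#'
#' Generates successive R-wave times for one trial. Each RR interval is the
#' base interval `60/mean_hr`, modulated sinusoidally to mimic respiratory
#' sinus arrhythmia (RSA), plus Gaussian beat-to-beat noise (SDNN),
#' truncated to stay positive:
#' `RR = base * (1 + rsa_amp * sin(2*pi*rsa_freq*t)) + N(0, sdnn)`.
#'
#' @param duration Trial window in seconds (default 60).
#' @param mean_hr Mean heart rate in beats per minute, in `[30, 180]`.
#' @param sdnn SD of the Gaussian RR noise in seconds (>= 0).
#' @param rsa_amp RSA modulation depth as a fraction of the base interval.
#' @param rsa_freq RSA frequency in Hz (typical breathing ~0.2-0.3 Hz).
#' @param seed Optional integer seed.
#' @return An [event_series()] with stream `"r_wave"`. The first beat falls
#'   one RR interval after the window start.
#' @export
simulate_rr_train <- function(duration = 60, mean_hr = 70, sdnn = 0.05,
                              rsa_amp = 0.05, rsa_freq = 0.25, seed = NULL) {
  if (mean_hr < 30 || mean_hr > 180) {
    stop("mean_hr outside the physiological range [30, 180] bpm", call. = FALSE)
  }
  if (sdnn < 0 || rsa_amp < 0 || rsa_freq < 0) {
    stop("sdnn, rsa_amp and rsa_freq must be non-negative", call. = FALSE)
  }
  base <- 60 / mean_hr
  with_seed(seed, {
    times <- numeric(ceiling(duration / base * 1.5) + 8L)
    t <- 0
    k <- 0L
    while (t <= duration) {
      rr <- base * (1 + rsa_amp * sin(2 * pi * rsa_freq * t)) +
        stats::rnorm(1L, 0, sdnn)
      rr <- max(rr, 1e-3)
      t <- t + rr
      if (t > duration) break
      k <- k + 1L
      times[k] <- t
    }
    event_series(times[seq_len(k)], "r_wave", duration = duration)
  })
}

#' Simulate a PPG foot train from an R-wave train
#'
#' Each R wave produces a pulse-wave inflection at the recording site after
#' one pulse transit time, plus Gaussian timing jitter. Pulse waves arriving
#' after the trial window are not recorded (acquisition stops at the trial
#' end). Exercises [estimate_ptt()].
#'
#' @param r_times [event_series()] of R-wave times.
#' @param ptt True pulse transit time in seconds, in `(0, 0.5)`.
#' @param jitter SD of Gaussian arrival-time jitter in seconds (>= 0).
#' @param seed Optional integer seed.
#' @return An [event_series()] with stream `"ppg_foot"`.
#' @export
simulate_ppg_train <- function(r_times, ptt = 0.2, jitter = 0.005, seed = NULL) {
  if (ptt <= 0 || ptt >= 0.5) {
    stop("ptt must lie in (0, 0.5) seconds", call. = FALSE)
  }
  if (jitter < 0) stop("jitter must be non-negative", call. = FALSE)
  r <- event_times(r_times)
  dur <- if (inherits(r_times, "event_series")) r_times$duration else 60
  if (!length(r)) {
    return(event_series(numeric(0), "ppg_foot", duration = dur))
  }
  with_seed(seed, {
    t <- sort(r + ptt + stats::rnorm(length(r), 0, jitter))
    t <- unique(t[t <= dur])
    event_series(t, "ppg_foot", duration = dur)
  })
}

#' Simulate the tone schedule of the auditory control trial
#'
#' The tone trial presents an average of 80 tones per minute — the
#' mid-point of the normal 60-100 bpm heart-rate range — with the per-trial
#' tone count jittered by +/- 10% and onsets paced by a sinusoidally
#' modulated presentation rate at 13 cycles/minute, mimicking respiratory
#' sinus arrhythmia at a normal breathing rate. The realised count `N` is
#' drawn uniformly on `round(nominal*(1-jitter_frac)) ..
#' round(nominal*(1+jitter_frac))`; the `N` onsets are then drawn i.i.d.
#' from the density proportional to `1 + mod_depth*sin(2*pi*f*t)` on
#' `[0, duration)` by inverse-CDF sampling, so exactly `N` tones land in the
#' window and the long-run onset rate carries the modulation.
#'
#' @param duration Trial window in seconds (default 60).
#' @param nominal_count Nominal mean number of tones per trial (default 80).
#' @param jitter_frac Per-trial count jitter as a fraction (default 0.10).
#' @param mod_cycles_per_min Rate-modulation frequency in cycles per minute
#'   (default 13).
#' @param mod_depth Modulation depth `a` of the rate `1 + a*sin(...)`
#'   (default 0.2).
#' @param seed Optional integer seed.
#' @return An [event_series()] with stream `"tone"`, strictly increasing
#'   times in `[0, duration)`.
#' @export
simulate_tone_schedule <- function(duration = 60, nominal_count = 80,
                                   jitter_frac = 0.10,
                                   mod_cycles_per_min = 13, mod_depth = 0.2,
                                   seed = NULL) {
  if (nominal_count < 1) stop("nominal_count must be >= 1", call. = FALSE)
  if (mod_depth < 0 || mod_depth >= 1) {
    stop("mod_depth must lie in [0, 1)", call. = FALSE)
  }
  f <- mod_cycles_per_min / 60  # Hz
  lo <- round(nominal_count * (1 - jitter_frac))
  hi <- round(nominal_count * (1 + jitter_frac))
  with_seed(seed, {
    n <- sample(lo:hi, 1L)
    # Inverse-CDF sampling from density proportional to 1 + a*sin(2*pi*f*t).
    # Cumulative intensity: L(t) = t + a/(2*pi*f) * (1 - cos(2*pi*f*t)).
    u <- sort(stats::runif(n)) * cum_intensity(duration, mod_depth, f)
    t <- invert_cum_intensity(u, duration, mod_depth, f)
    # Continuous draws tie with probability zero; enforce strictness anyway.
    while (anyDuplicated(t)) t <- sort(t + stats::runif(n, 0, 1e-9))
    event_series(pmin(t, duration - 1e-9), "tone", duration = duration)
  })
}

cum_intensity <- function(t, a, f) {
  t + a / (2 * pi * f) * (1 - cos(2 * pi * f * t))
}

# Numerical inverse of the cumulative intensity via grid interpolation
# followed by two Newton polishing steps (accuracy << 1 ms).
invert_cum_intensity <- function(u, duration, a, f) {
  grid <- seq(0, duration, length.out = 4096L)
  t <- stats::approx(cum_intensity(grid, a, f), grid, xout = u,
                     rule = 2)$y
  for (i in 1:2) {
    t <- t - (cum_intensity(t, a, f) - u) / (1 + a * sin(2 * pi * f * t))
    t <- pmin(pmax(t, 0), duration)
  }
  sort(t)
}

#' Estimate the rate-modulation frequency of tone schedules
#'
#' Bins tone onsets, averages the binned counts across trials, and returns
#' the frequency of the largest non-zero spectral peak of the mean rate, in
#' cycles per minute. Used to verify that generated schedules carry the
#' intended sinusoidal modulation.
#'
#' @param schedules List of tone [event_series()] (or numeric vectors).
#' @param bin Bin width in seconds (default 0.25).
#' @param duration Trial window in seconds (default 60).
#' @return Dominant modulation frequency in cycles per minute.
#' @export
tone_modulation_frequency <- function(schedules, bin = 0.25, duration = 60) {
  nb <- ceiling(duration / bin)
  counts <- Reduce(`+`, lapply(schedules, function(s) {
    t <- event_times(s)
    tabulate(pmin(floor(t / bin) + 1L, nb), nbins = nb)
  })) / length(schedules)
  spec <- Mod(stats::fft(counts - mean(counts)))^2
  half <- 2:floor(nb / 2 + 1)        # skip the DC component
  k <- which.max(spec[half])         # cycles per window among non-zero freqs
  k * 60 / duration
}

#' Perceptual profile: generative model of tapping behaviour
#'
#' Operationalises a participant's interoceptive (or auditory) sensitivity
#' as three mechanisms: each perceivable event is independently *detected*
#' with probability `p_detect`; a detected event yields a tap after a motor
#' delay `delay_mu` with timing noise `delay_sd`; and *spurious* taps
#' unrelated to any event arrive as a uniform Poisson stream at
#' `spurious_rate` taps/s. Condition-specific multipliers scale
#' `p_detect`, `delay_sd` and `spurious_rate` per task condition, encoding
#' how instructions (guessing allowed or not) and perturbation (breath
#' hold) change behaviour.
#'
#' @param p_detect Baseline detection probability per perceivable event.
#' @param delay_mu Mean tap delay after a detected event, seconds. The
#'   default 0 centres taps on the perceivable beat (systole onset), which
#'   reproduces the near-zero mean tap delays typical of this task.
#' @param delay_sd SD of the tap delay, seconds.
#' @param spurious_rate Baseline spurious tap rate, taps/s.
#' @param multipliers Named list of per-condition multiplier lists; each of
#'   `guessing`, `no_guessing`, `breath_hold`, `tone` may supply numeric
#'   `p_detect`, `delay_sd`, `spurious_rate` factors (default 1).
#' @return An object of class `perceptual_profile`.
#' @export
perceptual_profile <- function(p_detect, delay_mu = 0, delay_sd = 0.15,
                               spurious_rate = 0.1, multipliers = list()) {
  if (p_detect < 0 || p_detect > 1) {
    stop("p_detect must be a probability in [0, 1]", call. = FALSE)
  }
  if (delay_sd < 0 || spurious_rate < 0) {
    stop("delay_sd and spurious_rate must be non-negative", call. = FALSE)
  }
  conds <- c("guessing", "no_guessing", "breath_hold", "tone")
  bad <- setdiff(names(multipliers), conds)
  if (length(bad)) {
    stop(sprintf("unknown condition(s) in multipliers: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(p_detect = p_detect, delay_mu = delay_mu,
                 delay_sd = delay_sd, spurious_rate = spurious_rate,
                 multipliers = multipliers),
            class = "perceptual_profile")
}

# Resolve condition-effective parameters from a profile.
profile_for_condition <- function(profile, condition) {
  m <- profile$multipliers[[condition]] %||% list()
  list(
    p_detect = min(1, profile$p_detect * (m$p_detect %||% 1)),
    delay_mu = profile$delay_mu,
    delay_sd = profile$delay_sd * (m$delay_sd %||% 1),
    spurious_rate = profile$spurious_rate * (m$spurious_rate %||% 1)
  )
}

#' Simulate tap times from a perceptual profile
#'
#' Applies the detection + delay + spurious generative model of
#' [perceptual_profile()] to a train of perceivable events: detected events
#' yield a tap at `event + delay_mu + N(0, delay_sd)`; spurious taps are
#' Poisson-uniform over the window. The merged tap series is sorted and
#' clipped to `[0, duration]`. With `p_detect = 0` and a positive spurious
#' rate the taps are exactly the uniform law assumed by [simulate_null()].
#'
#' @param perceivable [event_series()] of perceivable beat (or tone) times.
#' @param profile A [perceptual_profile()].
#' @param condition Task condition selecting the profile multipliers.
#' @param duration Trial window in seconds (default 60).
#' @param seed Optional integer seed.
#' @return An [event_series()] with stream `"tap"`.
#' @export
simulate_taps <- function(perceivable, profile,
                          condition = c("guessing", "no_guessing",
                                        "breath_hold", "tone"),
                          duration = 60, seed = NULL) {
  stopifnot(inherits(profile, "perceptual_profile"))
  condition <- match.arg(condition)
  par <- profile_for_condition(profile, condition)
  ev <- event_times(perceivable)
  with_seed(seed, {
    detected <- ev[stats::runif(length(ev)) < par$p_detect]
    evoked <- detected + par$delay_mu +
      stats::rnorm(length(detected), 0, par$delay_sd)
    n_sp <- stats::rpois(1L, par$spurious_rate * duration)
    taps <- sort(c(evoked, stats::runif(n_sp, 0, duration)))
    taps <- unique(taps[taps >= 0 & taps <= duration])
    event_series(taps, "tap", duration = duration)
  })
}

#' Group templates for the synthetic cohort
#'
#' Bundles the generative parameters of one diagnostic group: a
#' [perceptual_profile()] for the heartbeat and tone trials, heart-rate
#' distribution parameters, the breath-hold heart-rate increment, rating
#' distributions, and the group's target interoceptive modulation ability
#' (IMA) — the expected change in beat-to-tap consistency per trial step.
#'
#' @param name Group label (`"healthy"`, `"dep_anx"`, `"sud"`).
#' @param profile A [perceptual_profile()].
#' @param target_ima Expected consistency slope across trials 1 to 3,
#'   z-units per step (descriptive of the profile; used by parameter-
#'   recovery checks).
#' @param hr_mean,hr_sd Mean and SD (bpm) of subjects' mean heart rate.
#' @param sdnn RR noise SD, seconds.
#' @param bh_hr_delta Heart-rate increment during breath hold, bpm.
#' @param ratings Named list per rating (`confidence`, `intensity`,
#'   `difficulty`) of per-condition mean vectors (guessing, no_guessing,
#'   breath_hold, tone); SD 15 on a 0-100 scale.
#' @return An object of class `group_template`.
#' @export
group_template <- function(name, profile, target_ima, hr_mean = 70,
                           hr_sd = 9, sdnn = 0.045, bh_hr_delta = 0,
                           ratings = NULL) {
  stopifnot(inherits(profile, "perceptual_profile"))
  structure(list(name = name, profile = profile, target_ima = target_ima,
                 hr_mean = hr_mean, hr_sd = hr_sd, sdnn = sdnn,
                 bh_hr_delta = bh_hr_delta,
                 ratings = ratings %||% default_ratings()),
            class = "group_template")
}

default_ratings <- function() {
  list(confidence = c(guessing = 35, no_guessing = 37, breath_hold = 50,
                      tone = 76),
       intensity = c(guessing = 25, no_guessing = 28, breath_hold = 45,
                     tone = 60),
       difficulty = c(guessing = 55, no_guessing = 62, breath_hold = 48,
                      tone = 22))
}

#' Default group templates
#'
#' The study conditions the simulator emulates. Healthy subjects improve
#' across the guessing, no-guessing, and breath-hold conditions — detection
#' probability rises and tap-timing noise falls — giving a target IMA slope
#' of 0.8 z-units per trial step (consistency means near 0, 0.8, 1.6).
#' Patient templates (depression/anxiety, substance use) keep trial-1
#' precision in every heartbeat condition: target slope 0. All groups tap
#' near-ceiling on the auditory tone trial. Guessing trials add a high
#' spurious tap rate (taps roughly at heart rate, mostly uninformed);
#' no-guessing and breath-hold trials have sparse spontaneous tapping.
#' Breath hold raises heart rate by ~4 bpm in the healthy and substance-use
#' templates. Parameter values were calibrated by simulation against the
#' group-mean consistency, tap-count and heart-rate profiles the analysis
#' is designed to detect.
#'
#' @return Named list of [group_template()] objects.
#' @export
default_templates <- function() {
  healthy <- perceptual_profile(
    p_detect = 0.28, delay_mu = 0, delay_sd = 0.275, spurious_rate = 0.15,
    multipliers = list(
      guessing = list(p_detect = 0, delay_sd = 1.00, spurious_rate = 6.2),
      no_guessing = list(p_detect = 1.00, delay_sd = 1.00, spurious_rate = 1),
      breath_hold = list(p_detect = 1.25, delay_sd = 0.214 / 0.275,
                         spurious_rate = 1),
      tone = list(p_detect = 0.95 / 0.28, delay_sd = 0.10 / 0.275,
                  spurious_rate = 0.05)
    ))
  patient <- perceptual_profile(
    p_detect = 0.28, delay_mu = 0, delay_sd = 0.335, spurious_rate = 0.15,
    multipliers = list(
      guessing = list(p_detect = 1.00, delay_sd = 0.300 / 0.335,
                      spurious_rate = 4.5),
      no_guessing = list(p_detect = 1.00, delay_sd = 1.00, spurious_rate = 1),
      breath_hold = list(p_detect = 1.00, delay_sd = 1.00, spurious_rate = 1),
      tone = list(p_detect = 0.95 / 0.28, delay_sd = 0.10 / 0.335,
                  spurious_rate = 0.05)
    ))
  list(
    healthy = group_template("healthy", healthy, target_ima = 0.8,
                             hr_mean = 66, bh_hr_delta = 4),
    dep_anx = group_template("dep_anx", patient, target_ima = 0,
                             hr_mean = 70, bh_hr_delta = 0),
    sud = group_template("sud", patient, target_ima = 0,
                         hr_mean = 70, bh_hr_delta = 4)
  )
}

#' Group template with a calibrated target IMA slope
#'
#' Returns a template whose expected beat-to-tap consistency means across
#' the guessing, no-guessing and breath-hold conditions are approximately
#' `(0, target_ima, 2 * target_ima)` — i.e. a true IMA slope of
#' `target_ima` z-units per trial step with a baseline of 0. The guessing
#' condition taps uniformly at random (detection probability 0), so its
#' expected consistency is 0 by construction; the tap-timing SDs of the
#' other conditions were calibrated by simulation under the default cohort
#' heart-rate distribution. Used for parameter-recovery checks of the
#' slope estimator; supported targets are 0, 0.3 and 0.8.
#'
#' @param target_ima True slope in z-units per trial step: 0, 0.3 or 0.8.
#' @param name Group label for the template (default `"healthy"`).
#' @return A [group_template()].
#' @export
ima_template <- function(target_ima, name = "healthy") {
  presets <- list(
    `0` = c(ng_sd = 0.425, bh_sd = 0.333, p = 0),     # p = 0: pure uniform
    `0.3` = c(ng_sd = 0.425, bh_sd = 0.333, p = 0.28),
    `0.8` = c(ng_sd = 0.275, bh_sd = 0.214, p = 0.28)
  )
  key <- as.character(target_ima)
  if (!key %in% names(presets)) {
    stop("calibrated targets are 0, 0.3 and 0.8 z-units per trial step",
         call. = FALSE)
  }
  pr <- presets[[key]]
  profile <- perceptual_profile(
    p_detect = unname(pr["p"]), delay_mu = 0, delay_sd = unname(pr["ng_sd"]),
    spurious_rate = 0.15,
    multipliers = list(
      guessing = list(p_detect = 0, spurious_rate = 6.2),
      no_guessing = list(p_detect = 1, delay_sd = 1),
      breath_hold = list(p_detect = 1.25,
                         delay_sd = unname(pr["bh_sd"] / pr["ng_sd"])),
      tone = list(p_detect = if (pr["p"] > 0) 0.95 / pr["p"] else 0,
                  delay_sd = unname(0.10 / pr["ng_sd"]),
                  spurious_rate = 0.05)
    ))
  group_template(name, profile, target_ima = target_ima, hr_mean = 68,
                 bh_hr_delta = 4)
}

#' Simulate a full synthetic cohort
#'
#' Generates, for each subject, all four trials (guessing, no-guessing,
#' breath-hold, tone): an R-wave train from the subject's heart-rate
#' parameters (with the template's breath-hold increment), a PPG foot train
#' at the subject's true pulse transit time, the tone schedule for the tone
#' trial, and taps from the group's perceptual profile. Subject-level
#' randomness is driven by sub-seeds derived deterministically from
#' `master_seed` and the subject's group and index, so cohorts are
#' reproducible and independent of generation order.
#'
#' @param n_per_group Named integer vector, e.g.
#'   `c(healthy = 50, dep_anx = 50, sud = 50)`; names must have templates.
#' @param templates Named list of [group_template()] (default
#'   [default_templates()]).
#' @param master_seed Integer master seed.
#' @param duration Trial window in seconds (default 60).
#' @return An object of class `cohort`: list with `records` (list of
#'   [trial_record()]), `metadata` (data frame: subject_id, group, age,
#'   sex, medicated, true mean HR, true PTT), and `params`.
#' @export
simulate_cohort <- function(n_per_group, templates = default_templates(),
                            master_seed = 1, duration = 60) {
  groups <- names(n_per_group)
  if (is.null(groups) || !all(nzchar(groups))) {
    stop("n_per_group must be a named vector of group sizes", call. = FALSE)
  }
  missing_tpl <- setdiff(groups, names(templates))
  if (length(missing_tpl)) {
    stop(sprintf("no template for group(s): %s",
                 paste(missing_tpl, collapse = ", ")), call. = FALSE)
  }
  conds <- c("guessing", "no_guessing", "breath_hold", "tone")
  records <- list()
  meta <- list()
  for (g in groups) {
    tpl <- templates[[g]]
    g_off <- 1000003L * match(g, c("healthy", "dep_anx", "sud", groups))[1L]
    for (i in seq_len(n_per_group[[g]])) {
      sid <- sprintf("%s_%03d", g, i)
      s0 <- derive_seed(master_seed, g_off + 16L * i)
      subj <- with_seed(s0, list(
        mean_hr = min(95, max(52, stats::rnorm(1L, tpl$hr_mean, tpl$hr_sd))),
        ptt = min(0.3, max(0.12, stats::rnorm(1L, 0.2, 0.02))),
        age = round(min(65, max(18, stats::rnorm(1L, 34, 10)))),
        sex = sample(c("female", "male"), 1L),
        medicated = g != "healthy" && stats::runif(1L) < 0.4
      ))
      for (ci in seq_along(conds)) {
        cond <- conds[ci]
        sc <- derive_seed(master_seed, g_off + 16L * i + ci)
        hr <- subj$mean_hr +
          if (cond == "breath_hold") tpl$bh_hr_delta else 0
        r <- simulate_rr_train(duration, mean_hr = hr, sdnn = tpl$sdnn,
                               rsa_amp = 0.05, rsa_freq = 0.25, seed = sc)
        ppg <- simulate_ppg_train(r, ptt = subj$ptt, jitter = 0.005,
                                  seed = derive_seed(sc, 1L))
        targets <- if (cond == "tone") {
          simulate_tone_schedule(duration, seed = derive_seed(sc, 2L))
        } else {
          perceivable_beats(r, subj$ptt)
        }
        taps <- simulate_taps(targets, tpl$profile, condition = cond,
                              duration = duration,
                              seed = derive_seed(sc, 3L))
        streams <- list(r, ppg, taps)
        if (cond == "tone") streams <- c(streams, list(targets))
        ratings <- with_seed(derive_seed(sc, 4L), vapply(
          c("confidence", "intensity", "difficulty"),
          function(r9) min(100, max(0, stats::rnorm(
            1L, tpl$ratings[[r9]][[cond]], 15))),
          numeric(1L)))
        records[[length(records) + 1L]] <- trial_record(
          subject_id = sid, group = g, condition = cond, streams = streams,
          confidence = ratings[["confidence"]],
          intensity = ratings[["intensity"]],
          difficulty = ratings[["difficulty"]], duration = duration)
      }
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = sid, group = g, age = subj$age, sex = subj$sex,
        medicated = subj$medicated, mean_hr = subj$mean_hr, ptt = subj$ptt,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(records = records, metadata = do.call(rbind, meta),
                 params = list(master_seed = master_seed,
                               n_per_group = as.list(n_per_group),
                               duration = duration)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d trial records\n",
              nrow(x$metadata), length(x$records)))
  invisible(x)
}
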