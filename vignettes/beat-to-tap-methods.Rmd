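---
title: "Methods: heart-rate-corrected beat-to-tap consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-rate-corrected beat-to-tap consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beattap)
```

## The measurement problem

In a heartbeat tapping task a participant presses a key every time they feel
a heartbeat, for a 60-s trial, under three conditions of increasing
interoceptive demand: tapping while *guessing* is allowed, tapping only to
*felt* beats (no guessing), and tapping during an inspiratory *breath hold*
that amplifies cardiac sensations. An auditory control trial replaces
heartbeats with tones. The question is how precisely taps are locked to the
cardiac cycle, and how that precision changes across conditions.

The naive precision measure — the standard deviation of the time differences
between each tap and its nearest heartbeat — is confounded by heart rate:
faster hearts leave shorter windows around each beat, so even a random
tapper looks more precise at 95 bpm than at 55 bpm. `beattap` implements a
Monte-Carlo correction for this confound and everything needed to analyse a
cohort around it.

## The consistency statistic

For one trial, let $e_1 < \dots < e_m$ be the perceivable-beat (or tone)
times and $t_1, \dots, t_n$ the taps. Each tap is assigned to the event
minimising $|t_i - e_j|$ (`assign_nearest()`), giving signed deltas
$d_i = t_i - e_{j(i)}$; the nearest-event rule, rather than
previous-event, keeps preemptive (anticipatory) taps interpretable. The
observed score is the sample SD $s_{obs}$ of the $d_i$
(`observed_delta_sd()`).

The null model asks: what would $s_{obs}$ look like if this participant had
tapped at random? `simulate_null()` draws, per replicate, $n$ taps i.i.d.
Uniform$[0, 60]$ — the participant's *actual* number of taps against the
trial's *actual* event train — and scores each replicate identically. Over
`n_sims = 1000` replicates this yields null moments $(\mu_0, \sigma_0)$, and
the trial's **beat-to-tap consistency** is

$$ z = \frac{\mu_0 - s_{obs}}{\sigma_0}, $$

so larger $z$ means tapping more temporally consistent than chance
(`beat_to_tap_consistency()`). Because the null carries the trial's own
event train and tap count, $z$ is corrected for heart rate, heartbeat
variability, and tap count; under random tapping it has mean 0 and unit
variance by construction, which the test suite verifies on 2000 simulated
subjects along with the decorrelation property (the raw $s_{obs}$ correlates
negatively with heart rate; $z$ does not). The same statistic on the tone
trial is the tone-to-tap consistency (TTC), a control for general
stimulus-response tendencies.

Trials with fewer than 2 taps or 2 events cannot be scored; they are
returned flagged invalid rather than as errors, and the cohort pipeline
tallies them in an exclusion log.

## Perceivable beats and pulse transit time

A heartbeat cannot be felt before the pressure wave arrives, so events are
placed at the onset of systole: R-wave times shifted by the pulse transit
time (PTT). `estimate_ptt()` matches each pulse-wave (PPG foot) event to the
nearest preceding R wave with a delay in (0, 1.0 s] and takes the median
delay. The 1-s matching window exceeds any physiological ear PTT; the
matching rule itself is a package choice since only "corresponding" pairs
are implied by the task design. With fewer than `min_pairs = 5` matched
pairs the estimator returns the standard ear-site fallback of 0.200 s — a
median over fewer beats is too unstable to prefer over the population
value. Because the null uses the same (shifted) event train, a constant
error in PTT leaves $z$ unchanged; PTT mainly matters for the sign and
interpretation of mean tap delay.

## Secondary measures

Counting accuracy adapts the classical heartbeat-counting formula with the
tap count in place of the reported count:
$\max\{0,\, 1 - |n_{beats} - n_{taps}|/n_{beats}\}$. Clipping at 0 keeps the
score a proportion; whether negative values should instead be retained is
undecidable from group summaries alone, so the clip is a stated package
convention. Mean signed delay (`mean_delay()`) summarises reaction-time
offsets that $z$ deliberately ignores.

## From trials to groups

`compute_trial_metrics()` scores every subject × condition.
`ima_slopes()` condenses the three heartbeat conditions (coded 1 =
guessing, 2 = no guessing, 3 = breath hold) into one per-subject
least-squares slope of $z$ on trial index — the interoceptive modulation
ability (IMA). Subjects with fewer than two valid heartbeat conditions are
marked non-estimable and excluded with a recorded reason.

Two refinements are available. `shrinkage = TRUE` applies a two-stage
random-coefficient approximation of a mixed model: slopes are shrunk toward
the grand mean with reliability weights $\tau^2/(\tau^2 + v_i)$, where
$v_i$ uses the residual variance pooled across subjects (with three points
per subject, per-subject variances have 1 df and are far too noisy to
weight by) and $\tau^2$ is the method-of-moments between-subject variance.
A unit test checks that these shrunken slopes track `lme4` random-slope
BLUPs. `ttc_adjust = TRUE` residualises $z$ on TTC across observations
before slope fitting, removing variance shared with the exteroceptive
control task; residualising per observation (rather than per subject) was
chosen because TTC is a single subject-level covariate and the
per-observation regression is the direct analogue of entering it as a fixed
effect.

Group differences in IMA are tested by `group_condition_contrast()`: the
statistic is the absolute difference in group mean slopes (two groups) or
the one-way F ratio (three), with a null built by permuting group labels
across subjects and $p = (1 + \#\{perm \ge obs\})/(n_{perms}+1)$, floored
at $1/(n_{perms}+1)$ with a default of 10,000 permutations. This replaces a
covariate-adjusted linear mixed model on purpose: the permutation test is
exact under exchangeability, assumption-light, and keeps the package's
inferential machinery transparent; covariate adjustment beyond TTC (age,
sex, medication) is left to the user's own modelling on the exported
tables. `breath_hold_check()` verifies the manipulation moved what it
should: paired increases in tap count, heart rate, confidence and intensity,
and decreased difficulty, from the no-guessing to the breath-hold condition.

For exploratory multi-learner analyses, `aggregate_variable_importance()`
min-max scales each method's importance scores to [0, 100] and averages
them weighted by each method's predictive performance; the learners
themselves are standard fare and out of scope here.

## The synthetic cohort

No physiological recordings ship with the package; `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes, so
every stage can be validated by parameter recovery.

* **Heartbeats** (`simulate_rr_train()`): RR intervals
  $60/\mathrm{HR}\cdot(1 + a\,\sin 2\pi f t) + \mathcal{N}(0,
  \mathrm{SDNN})$, truncated positive; defaults SDNN 45 ms, RSA depth 0.05
  at 0.25 Hz, subject mean HR drawn from the group template (healthy 66
  bpm, patients 70 bpm, SD 9), giving 55–80 beats per trial. Breath hold
  adds +4 bpm in the healthy and substance-use templates.
* **Pulse waves** (`simulate_ppg_train()`): R times + subject PTT
  ($\mathcal{N}(0.20, 0.02^2)$ s, truncated to [0.12, 0.30]) + 5 ms jitter.
* **Tones** (`simulate_tone_schedule()`): per-trial count uniform on
  72…88 (nominal 80 ± 10%), onsets drawn by inverse-CDF sampling from a
  rate $\propto 1 + 0.2\sin(2\pi t \cdot 13/60)$ — 13 cycles/minute,
  mimicking respiratory sinus arrhythmia; the modulation depth 0.2 is a
  package default since only the frequency is part of the task design.
* **Taps** (`simulate_taps()`): each perceivable beat is detected with
  probability `p_detect`; detected beats yield a tap at beat +
  $\mathcal{N}(\mu_{delay}, \sigma_{delay}^2)$; spurious taps arrive
  Poisson-uniformly. `delay_mu = 0` by default: mean tap delays in this
  task are empirically near zero once taps are referenced to systole onset,
  and a nonzero mean would add a mixture-mean artefact to trials that blend
  evoked and spurious taps.

Group templates were calibrated once, by simulation under the default
heart-rate distribution, so that expected condition-mean consistency is
approximately {0, 0.8, 1.6} for the healthy template (IMA slope 0.8 z-units
per step, rising detection 0 → 0.28 → 0.35 and falling timing noise
275 → 214 ms) and flat ≈ 0.45 for both patient templates (IMA 0), with
near-ceiling tone tapping (z ≈ 8) and per-condition tap counts matching the
task's typical profile (guessing ≈ 60 mostly spurious taps, no-guessing ≈
27, breath-hold ≈ 33, tone ≈ 76). `ima_template()` exposes calibrated
presets with true slopes 0, 0.3 and 0.8 for parameter-recovery studies; the
slope-0 preset taps uniformly at random, making it exactly the null's
generative law.

What the generator does **not** emulate: real ECG/PPG morphology and
detection errors (the package consumes event times by design), missing
trials and artefact-driven exclusions, tap–tap refractoriness, fatigue or
learning within a trial, medication effects, and any true covariate
structure (age/sex enter the metadata as noise). Passing recovery tests
therefore shows the *estimators* are sound under the assumed generative
model, not that the model captures every property of clinical recordings.

## Numerical conventions and reproducibility

* Midpoint ties in nearest-event assignment break toward the earlier event
  (deterministic; measure-zero under continuous time).
* Sample (n−1) SDs throughout, for both observed and null-replicate SDs.
* Null taps are placed on [0, duration], not the beat span; window
  boundaries are closed for beat counting; events shifted past the trial
  end by the PTT are retained.
* One master seed drives everything; per-subject and per-trial sub-seeds
  are derived with a Lehmer-style hash (`beattap:::derive_seed`), so cohort
  generation is order-independent and all results are bit-reproducible.
  Library code restores the caller's RNG state.
* Problem sizes: unit and property tests run at reduced Monte-Carlo sizes
  (null `n_sims` 150–500, permutations 999) where the property under test
  is insensitive to null-moment noise — permutation validity and power are;
  per-trial z values are reported with the full 1000-replicate default. The
  cohort-scale checks use 2000 subjects for null calibration, 200/500
  repetitions for power/type-I recovery, and 100 healthy + 500 patient
  subjects for the condition-profile check; these sizes put Monte-Carlo
  noise well inside the asserted bands.

## Known limitations

* The Z-score corrects location and scale of the null but not its shape;
  extreme consistencies (tone trials, z ≈ 8–10) are many null SDs out,
  where the Gaussian reading of "z" is only a ranking, not a tail
  probability.
* With three conditions, per-subject slopes have one residual df;
  inference leans on the group level, and the shrinkage option exists
  precisely because individual slopes are noisy.
* The permutation contrast assumes exchangeable subjects under the null;
  confounding by covariates that differ between groups must be handled
  upstream (e.g. residualisation) or by stratified extensions.
* Uniform-random tapping is the only implemented null; alternatives
  (inter-tap-interval shuffles, circular shifts) would slot behind the same
  interface but are not provided.
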