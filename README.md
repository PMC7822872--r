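# beattap

Analysis toolkit for **heartbeat tapping** interoception experiments: a
participant taps along with their felt heartbeats for 60-s trials under
conditions of increasing interoceptive demand (guessing allowed → no
guessing → inspiratory breath hold), plus an auditory tone control trial.
`beattap` turns the recorded event times (ECG R waves, PPG pulse waves,
taps, tones) into heart-rate-corrected perceptual scores and group-level
inference, and ships a synthetic-cohort simulator so the whole pipeline can
be validated by parameter recovery.

## The statistic

The raw precision measure — the SD of the signed time differences
$d_i = t_i - e_{j(i)}$ between each tap and its nearest perceivable beat —
is confounded by heart rate: faster hearts leave shorter windows around each
beat, so random tapping looks more precise at high heart rates. `beattap`
scores each trial against a Monte-Carlo null in which the participant's
actual number of taps is placed uniformly at random on the trial and scored
against the participant's actual beat train (1000 replicates). With null
moments $(\mu_0, \sigma_0)$ of the replicate SDs, the **beat-to-tap
consistency** is

$$ z = \frac{\mu_0 - s_{obs}}{\sigma_0} $$

— larger z means tapping more consistently locked to the cardiac cycle than
chance, with mean 0 and unit variance under random tapping, uncorrelated
with heart rate and tap count by construction. Perceivable beats are placed
at systole onset: R-wave times shifted by the pulse transit time, estimated
as the median R-to-pulse-wave delay (0.200 s ear-site fallback when too few
pairs match). Per-subject **interoceptive modulation ability (IMA)** is the
slope of z across the three heartbeat conditions (coded 1, 2, 3), and group
differences in IMA are tested by label permutation.

## Worked example

```r
library(beattap)

co <- simulate_cohort(c(healthy = 30, dep_anx = 30), master_seed = 7)
metrics <- compute_trial_metrics(co, seed = 8)
valid <- metrics[metrics$valid, ]
round(tapply(valid$z, list(valid$group, valid$condition), mean), 2)
#>         breath_hold guessing no_guessing tone
#> dep_anx        0.47     0.27        0.26 7.68
#> healthy        1.34     0.16        0.80 7.37

slopes <- ima_slopes(metrics)
group_condition_contrast(slopes, c("healthy", "dep_anx"),
                         n_perms = 10000, seed = 9)
#> <contrast_result> healthy vs dep_anx: statistic=0.4913 perm_p=0.017 (n_perms=10000)
#>    group  n mean_slope        se      ci_lo     ci_hi
#>  healthy 30 0.58875939 0.1391963  0.3159346 0.8615842
#>  dep_anx 30 0.09742469 0.1435672 -0.1839670 0.3788164
```

The healthy group's consistency rises from chance level in the guessing
condition to z ≈ 1.3 under breath hold, while the simulated patient group
stays flat around z ≈ 0.3–0.5; everyone is near-ceiling on the audible
tones (z ≈ 7–8). The permutation test (p = 0.017) detects the difference in
modulation slopes at n = 30 per group. The breath-hold manipulation check
confirms the perturbation moved what it should in the healthy group:

```r
breath_hold_check(metrics[metrics$group == "healthy", ])
#>      measure n_pairs mean_diff     t df        p
#> 1     n_taps      30      6.73  8.56 29 1.97e-09
#> 2 heart_rate      30      4.07 30.11 29 1.98e-23
#> 3 confidence      30     14.55  4.81 29 4.31e-05
#> 4  intensity      30     13.73  5.08 29 2.05e-05
#> 5 difficulty      30    -21.27 -4.81 29 4.25e-05
```

Real recordings enter through `read_event_table()` (long CSV: `subject_id,
group, condition, stream, time_s`), and `report()` writes the cohort table,
exclusion log, group × condition means, contrasts and provenance to a
directory. A thin command-line wrapper with `simulate` and `analyze`
subcommands lives in `inst/scripts/beattap-cli.R`.

See `vignettes/beat-to-tap-methods.Rmd` for the model, the null
construction, the synthetic-cohort generative model and its calibration,
and the package's numerical conventions.

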