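# periglyc

Peri-exercise glycemia analysis for people with type 1 diabetes using
automated insulin delivery (AID) systems: event-anchored segmentation of
continuous glucose monitoring (CGM) time around free-living physical
activity (PA) sessions, glucose band metrics per window, classification of
logbook-reported hypoglycemia and behavioural adjustments, and a
mixed-effects model linking guideline deviations to hypoglycemia risk — plus
a seeded synthetic cohort generator for testing the whole pipeline at
realistic scale.

## Who this is for

Researchers analyzing paired CGM + exercise-logbook data (or building
methods for such data) who need reproducible answers to questions like: *how
much time below range do participants accumulate during and after exercise
compared with baseline? how often do reported hypoglycemia episodes occur
per session and per participant? are late temporary-target activation,
pre-exercise snacking, or large intra-exercise carbohydrate intakes
associated with hypoglycemia?*

## The model in brief

**Windows.** Each participant's timeline is partitioned, at minute
resolution with half-open intervals, into `PRE` (−2 h), `DURING`, `EARLY`
(+3 h post-exercise), `LATE` (to 08:00 next day or the next pre-window) and
`NONEX`, with priority `DURING > EARLY > PRE > LATE > NONEX`.

**Metrics.** Readings are pooled per window class into the consensus bands
`<54 | 54–69 | 70–180 | 181–250 | >250` mg/dL, giving TBR / TIR / TAR per
window.

**Episodes & adjustments.** Logbook episodes are levelled at the 54 mg/dL
threshold; sessions are flagged for three guideline deviations (temporary
target not set ≥1 h ahead; snack within 1 h before; any single
during-exercise intake >20 g).

**Association.** Per-session hypoglycemia is modelled as

```
logit P(y_ij = 1 | b_i) = beta0 + beta' f_ij + b_i,   b_i ~ N(0, sigma^2)
```

with participant random intercept `b_i`, fitted by adaptive Gauss–Hermite
quadrature (20 nodes; validated against `lme4::glmer` and a closed-form
odds-ratio case); Wald inference at two-sided alpha 0.05.

## Worked example

Simulate the default calibrated cohort (86 participants, 30 days, ~950
sessions) and run the full analysis:

```r
library(periglyc)

cfg     <- default_cohort_config(seed = 1)
cohort  <- generate_cohort(cfg)
windows <- cohort_window_partition(cohort$sessions)
traces  <- synthesize_traces(cfg, cohort$sessions, windows)

metrics_table(compute_window_metrics(traces, windows))
```

```
 window_class n_readings   hours pct_lt54 pct_54_69 pct_70_180 pct_181_250
          PRE      16536  1378.0        0         1         74          20
       DURING      14884  1240.3        2         4         70          19
        EARLY      24804  2067.0        1         4         69          21
         LATE     147169 12264.1        1         3         74          18
        NONEX    1160305 96692.1        1         2         73          19
 pct_gt250 tbr_total tir tar_total
         5         1  74        25
         5         6  70        24
         5         5  69        26
         4         4  74        22
         5         3  73        24
```

Time below range rises from ~1% before exercise to ~6% during and ~5% in
early recovery, stays elevated (~4%) through late recovery, and sits at ~3%
in non-exercise time — the risk signature the windowing is designed to
expose.

```r
aggregate_episode_stats(cohort$sessions, cohort$episodes)
```

```
Hypoglycemia episode summary (914 sessions, 86 participants)
  sessions with any episode : 173 (19%)
  level 1 / level 2 sessions: 12% / 7%
  symptomatic (of hypo)     : 68%
  interruption temp/perm    : 21% / 7%
  participants any / level 2: 79% / 37%
  by activity type (%):
  aerobic anaerobic     mixed 
       19        11        22 
```

About one session in five contains a reported episode; anaerobic sessions
carry a visibly lower rate than aerobic/mixed ones; roughly a third of
participants accumulate at least one level-2 (<54 mg/dL) episode over the
month.

```r
fits <- fit_deviation_models(cohort)
fits$joint
```

```
Random-intercept logistic regression (AGQ, 20 nodes)
  799 sessions, 86 participants; sigma_intercept = 0.879; converged
                       term estimate     se     or ci_lower ci_upper   p_value
                (Intercept)  -1.6600 0.2248 0.1901   0.1223   0.2953 1.508e-13
     late_or_no_temp_target  -0.1589 0.2207 0.8531   0.5535   1.3150 4.715e-01
     snack_within_1h_before   0.4662 0.2468 1.5940   0.9827   2.5850 5.886e-02
 single_intake_gt20g_during   0.1182 0.3171 1.1250   0.6045   2.0950 7.093e-01
```

With the default calibration no deviation flag is significantly associated
with hypoglycemia (all CIs cover 1), matching the generator's zero-effect
default. `run_report()` chains all stages and writes `metrics.csv`,
`episode_stats.json`, `adjustments.csv`, `association.json`, `windows.csv`
and a reconciling `run.log`; `exec/periglyc` exposes the same pipeline as a
command-line tool with `simulate` / `report` / per-stage subcommands.

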