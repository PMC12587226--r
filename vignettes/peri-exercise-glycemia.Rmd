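---
title: "Peri-exercise glycemia: windows, metrics, and the deviation-hypoglycemia model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-exercise glycemia: windows, metrics, and the deviation-hypoglycemia model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periglyc)
```

## The problem

People with type 1 diabetes who use automated insulin delivery (AID) systems
still face a substantial hypoglycemia risk around physical activity (PA):
aerobic work consumes glucose while exogenous insulin remains active, and
the mitigations available to the user — raising the glucose set-point
("temporary target") ahead of exercise, and timed carbohydrate intake — are
easy to apply too late or in the wrong dose. Quantifying that risk from
free-living data requires three ingredients this package provides:

1. an **event-anchored segmentation** of continuous glucose monitoring (CGM)
   time into peri-exercise windows,
2. **glucose band metrics** (time below / in / above range) pooled per
   window class, and
3. a **mixed-effects logistic regression** linking per-session
   guideline-deviation flags to reported hypoglycemia, with a participant
   random intercept for repeated sessions.

Because free-living CGM + logbook datasets of this kind are generally not
redistributable, the package also ships a **seeded synthetic cohort
generator** whose defaults emulate a one-month observational cohort of 86
adults on AID systems logging roughly 950 PA sessions. All pipeline code is
exercised end-to-end against data of that shape.

## Window model

Five half-open, minute-resolution window classes partition each
participant's study span:

| class  | definition |
|--------|------------|
| PRE    | up to 2 h before a session start |
| DURING | the logged session interval |
| EARLY  | up to 3 h after a session end (early recovery) |
| LATE   | from the end of early recovery to the next 08:00 clock time, or to the next session's pre-window if sessions are closely spaced |
| NONEX  | all remaining time |

When windows of different sessions overlap, priority is
`DURING > EARLY > PRE > LATE > NONEX`. Only LATE is subordinated to the next
session's pre-window; early recovery is a fixed +3 h, so EARLY outranks a
following session's PRE. This rule set makes the labelling total without
needing a numeric definition of "closely spaced". Ownership ties are
resolved toward the most recent qualifying session (latest end for
EARLY/LATE, soonest upcoming start for PRE). A timestamp exactly on a
boundary belongs to the later window. If early recovery ends after 08:00,
the late-recovery cutoff rolls to 08:00 the following day. The study span
runs from 15 days before the first session to 15 days after the last one
(matching a typical pump/CGM download), and the whole remainder counts as
non-exercise time.

The partition is computed twice in the test-suite: once by interval
arithmetic (`build_window_partition()`, the production path) and once by
brute-force per-minute labelling (`label_timepoint()`, a direct transcription
of the rules above); the two must agree minute-for-minute on randomized
session sets, and every partition must conserve the span exactly.

```{r windows-demo}
ss <- data.frame(session_id = "S1", participant_id = "P001",
                 start = pg_time("2024-06-02 10:00"), duration_hours = 1.5)
build_window_partition(ss, "2024-06-01", "2024-06-04")[, 1:3]
```

## Glucose bands and pooling

Band thresholds follow the international consensus CGM targets, with
boundary inclusivity forced by the conventional definitions "below 70",
"70–180", "above 180":

* `<54` (level-2 low), `54–69` (level-1 low): together TBR (< 70 mg/dL);
* `70–180` inclusive: TIR;
* `181–250` (level-1 high), `>250` (level-2 high): together TAR.

`compute_window_metrics()` assigns each reading to the unique window
containing its timestamp and pools **reading-weighted** percentages per
window class over all participants and sessions — the natural estimate of
"percentage of time" on a 5-minute grid, with no interpolation across gaps.
Because it is not universal which pooling convention a given study uses, a
per-participant-averaged alternative is available via
`pooling = "participants"`. Classes with zero readings report `NA`
percentages rather than zeros; readings outside every window are excluded
and counted in a warning.

## Episodes and adjustments

Logbook-reported hypoglycemia episodes are classified level 2 when the
lowest recorded glucose is below 54 mg/dL, level 1 otherwise. Episodes
reported on symptoms alone (no reading) are assigned level 1 by convention
and *flagged* (`level_imputed`) rather than silently classified — the
analyst can exclude them. A session counts as hypoglycemic with at least one
episode in any phase; participant-level prevalence uses "at least one over
the study". Stratified rates (activity type; modified Borg categories
nothing/low/moderate/high crossed with level) use complete-case denominators
per stratum.

Behavioural adjustments are categorized per session:

* temporary target: activation at least 1 h before start (offset
  `<= -60` min — "at least", so exactly 60 min counts as early), less than
  1 h before or during, or none;
* carbohydrate intake before (window `(0, 120]` min pre-start) and during
  the session, each as a list of (offset, grams) events.

Three guideline-deviation flags follow: temporary target not activated at
least 1 h ahead; any snack within the hour before start; any single
during-exercise intake strictly above 20 g (exactly 20 g is compliant).
Temporary-target summaries use sessions with non-missing adjustment data as
denominator; carbohydrate summaries use all sessions, mirroring how the two
logbook blocks are recorded. Medians and IQRs use linear interpolation
(type-7 quantiles) over sessions with intake.

## The association model

Per-session hypoglycemia is regressed on the deviation flags with a
participant random intercept:

$$\operatorname{logit} P(y_{ij}=1 \mid b_i) = \beta_0 + \beta^\top f_{ij} + b_i,
\qquad b_i \sim N(0, \sigma^2).$$

The marginal likelihood is maximized by **adaptive Gauss–Hermite
quadrature**: per participant the integrand is recentred at its mode and
rescaled by the local curvature before applying the quadrature rule, so 20
nodes are ample even for large cluster sizes (estimates move by less than
$10^{-3}$ between 20 and 40 nodes on cohort-sized problems, a property the
test-suite asserts). Inference is Wald at two-sided $\alpha = 0.05$; flags
are fitted jointly (one model, three effects) and singly (three one-flag
models), and no multiple-testing correction is applied (stated in the
output metadata). Non-convergence, boundary $\hat\sigma \approx 0$ with a
flat information direction, and likely separation (absolute log-odds above
10) are reported via `converged = FALSE`, never silently. Sessions whose
temporary-target data were not recorded have an undefined first flag and are
dropped (complete-case); the count is reported.

The implementation is validated in tests against `lme4::glmer` (nAGQ = 20)
as an independent oracle, and against the closed-form sample odds ratio in a
perfectly balanced zero-heterogeneity design, where the mixed-model MLE
must collapse to $(20 \cdot 90)/(80 \cdot 10) = 2.25$.

## The synthetic cohort generator

`default_cohort_config()` encodes the study conditions the package targets:
86 participants followed for 30 days, 2–3 sessions per week (uniform per
week, partial weeks thinned binomially, ~920 sessions expected), session
start uniform 07:00–21:00, duration truncated-normal (mean 1.5 h, SD 1.1 h,
minimum 15 min, capped at 8 h so nights stay session-free), activity type
aerobic/anaerobic/mixed at 75/9/16%, Borg categories at 2/27/62/9%.

**CGM band process.** Within each labeled window, consecutive readings
follow a stay-or-redraw chain: with probability `cgm_persistence` the
previous band is kept, otherwise the band is redrawn from the window class's
configured occupancy. The chain restarts from the occupancy at every window
boundary, so *every* reading's marginal band distribution equals the
configured occupancy exactly — no carryover bias between window classes.
Within-band values are uniform integers (all downstream metrics depend only
on band membership). Default occupancies put total TBR at 1% (pre), 6%
(during), 5% (early recovery), 4% (late recovery) and 3% (non-exercise,
with TIR 73%); the level-1/level-2 splits within TBR and TAR for windows
where only totals are conventionally reported are free choices of the
calibration. One printed-source rounding wrinkle: the late-recovery totals
4 + 76 + 22 exceed 100, so the default keeps TBR = 4 and TAR = 22 and sets
TIR = 74.

**Why persistence defaults to 0.1.** For a stationary band process with
lag-1 autocorrelation $\rho$, the variance of the empirical occupancy over
$n$ readings is inflated by roughly $(1+\rho)/(1-\rho)$ relative to
binomial. The package's calibration-recovery tests (and the acceptance
tolerances) are stated in *binomial* standard errors at the realized read
count; at $\rho = 0.9$ the inflation factor is 19 and a 3-binomial-SE band
corresponds to only 0.7 true SDs — the recovery property would fail for
half of all seeds *at perfect calibration*. At $\rho = 0.1$ the inflation is
1.22 and 3 binomial SEs are 2.7 true SDs. Users wanting visually smoother
traces can raise `cgm_persistence`, accepting wider Monte-Carlo bands.

**Session-level CGM missingness.** A fraction (default 240/954) of sessions
lose all readings over [start − 2 h, end + 3 h], emulating whole sessions
without a usable download; missingness is session-level because availability
is naturally counted per session.

**Hypoglycemia outcome.** Sessions draw any-hypoglycemia from a logistic
model with type-specific marginal rates (aerobic 20%, anaerobic 12%, mixed
21%), a participant random intercept (SD 1.0), and the deviation-flag
effects (zero by default — matching the finding that none of the deviations
was significantly associated with hypoglycemia in the emulated setting).
Intercepts are *attenuation-corrected* by numeric integration
(`marginal_logit()`) so the configured rates are marginal rates, not
conditional-on-$b_i = 0$ rates. Given hypoglycemia, the episode is level 2
via a second logistic with marginal share 1/3 and its own participant effect
(SD 2.0), representing stable inter-individual differences in hypoglycemia
depth/awareness. This two-component heterogeneity reproduces all three
prevalence scales at once — about 20% of sessions with an episode, about
38% of participants with a level-2 episode, and about 80% with any episode
over the month — while keeping the seed-to-seed SD of the session-level
rate near binomial (~1.7 points), which a single large intercept SD would
not. Episode descriptors (phase, symptom class at 10/13/42/35% with
asymptomatic episodes detected by CGM/capillary only, interruption at
69/19/12%, a 10% chance that a symptomatic level-1 episode lacks a reading)
are drawn independently.

**Adjustments.** Temporary-target categories at 27/46/27% with offsets
uniform within the category's range; 13.6% of sessions have the
temporary-target block unrecorded. Pre-exercise intake in 36% of sessions
(one event, log-normal grams, median 20 g); during-exercise intake in 27%
(1–3 events at 45/38.5/16.5%, event grams log-normal with median ~15.6 g),
which jointly yield a session-total median near 25.5 g while only ~10% of
all sessions contain a single event above 20 g — matching the seemingly
contradictory pair "median total above 20 g" and "few single intakes above
20 g".

**Reproducibility.** One master seed; per-participant substreams are derived
by a counter scheme (`derive_seed()`), so growing the cohort never
reshuffles earlier participants, and identical configs produce
byte-identical files.

## What the generator does and does not emulate

The generator targets *statistical structure*: window-conditional band
occupancies, logbook prevalences, and the clustered binary outcome. It is
not a physiological simulator — there are no insulin–glucose dynamics, no
pump-algorithm behaviour, no within-day glucose rhythms beyond the
window-conditional occupancies, and glucose values within a band are
uniform. Consequently, passing calibration-recovery tests demonstrates that
the segmentation, metric, classification and model code measure what they
claim on data of realistic shape and size; it does not validate the
pipeline against physiological CGM waveforms (e.g. sensor drift,
compression artifacts, meal excursions).

## Numerical choices and problem sizes

* Timestamps are timezone-naive local clock time at minute resolution; DST
  is out of scope (synthetic data never cross a transition).
* Quantiles: type 7 (linear interpolation). Percentages are reported on the
  0–100 scale; console tables round to integers, file outputs keep full
  precision.
* The quadrature default is 20 nodes; the optimizer is BFGS on
  $(\beta, \log\sigma)$ with the scale parameter bounded away from overflow,
  and standard errors come from the observed information at the optimum.
* Test-suite problem sizes: structural tests run 6-participant, 14-day
  cohorts (seconds); the calibration-recovery test runs the full 86 × 30-day
  cohort (~1.4 M readings, under a minute); the type-I-error study runs 400
  reduced cohorts of 30 participants × ~10 sessions; parameter recovery
  runs 100 cohorts of 86 participants at known effect sizes.

## Known limitations

* The deviation flags and the outcome are generated independently given the
  configured effects; real behaviour is confounded (riskier sessions invite
  more adjustments), so the zero-effect default should be read as a
  calibration convention, not a causal claim.
* Whether a carbohydrate intake was announced to the AID system is not
  modelled; the snack flag tests timing only.
* Borg intensity influences nothing in the generator by default (the
  intensity gradients of the emulated setting are not separately
  calibrated), though the episode tables stratify by it.
* Device comparisons are deliberately out of scope; pump brand exists only
  as a participant attribute.
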