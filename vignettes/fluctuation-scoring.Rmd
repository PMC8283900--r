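---
title: "Scoring time in bradykinesia and dyskinesia and classifying motor fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring time in bradykinesia and dyskinesia and classifying motor fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkgfluct)
```

## The measurement problem

Wrist-worn movement loggers such as the Parkinson's KinetiGraph produce a
bradykinesia score (BKS) and a dyskinesia score (DKS) for every 2-minute
epoch over a multi-day recording (usually 6 days). Clinically, the questions
asked of such a recording are not "what is the average score" but:

* How much of the waking day is the person *above target* for bradykinesia
  (PTB) or dyskinesia (PTD)?
* Does the first levodopa dose of the day produce a measurable response, and
  does that response *wear off* before the next dose?
* Which of six fluctuator phenotypes does the person express?

This package implements that analysis chain end to end, plus a synthetic
cohort generator with known ground truth so that every stage can be
validated without access to device recordings.

## Masks: which epochs count

All summary scores pool epochs from the daytime window 09:00-18:00
(half-open, so exactly 270 two-minute epochs per fully recorded day) across
all recorded days, after removing epochs where the logger was not worn.
Three further masks matter:

* **Sleep.** BKS at or above 80 is treated as sleep. The source definitions
  are inconsistent at the boundary point itself (sleep is "BKS >= 80" while
  the median BKS pools "BKS <= 80"); we use one sleep mask, `bks >= 80`,
  consistently, so the median pools scores strictly below 80. The choice
  affects a measure-zero set of scores.
* **Inactivity.** An epoch is inactive when the centred 30-minute
  (15-epoch) moving median of BKS is strictly greater than 40: so few
  movements occur that bradykinesia cannot be assessed. The moving median is
  unweighted ("centre weighted" in the source vocabulary has no published
  weighting scheme); the window truncates at recording edges rather than
  dropping them, and absent epochs are skipped, never imputed.
* **Daytime.** Half-open `[09:00, 18:00)`. Closing the interval at the left
  end only is what makes the 270-epochs-per-day arithmetic exact.

`median_bks()` uses worn, daytime, non-sleep epochs; `active_median_bks()`
and PTB additionally drop inactivity; `median_dks()` and PTD use worn
daytime epochs.

## The severity scale and PTB

BKS maps to a continuous 0-5.5 severity level through a monotone
piecewise-linear calibration. Integer levels correspond to fixed
UPDRS-III intervals (0-10, 10-22.5, 22.5-35, 35-47.5, 47.5-60, >= 60 for
levels 0-5); the continuous scale is linear at 12.5 UPDRS points per level
and anchored so that severity 2.5 = BKS 26 = UPDRS III 35, the in/out-of-
target boundary. Only that anchor is fixed by published data. The remaining
default anchors -- (0, 0), (23, 2.26), (40, 4.0), (80, 5.5) -- are package
defaults chosen so the other published score boundaries land where the
scale expects them: BKS 23 sits just inside target (elevated PTB begins
near there), and BKS 80 (sleep) tops out the scale. The full epoch-level
model behind the original scale is unpublished, so the calibration is a
user-replaceable table (`severity_calibration()`, YAML-configurable) and
every downstream quantity is defined relative to it.

Integer levels bin the UPDRS equivalent with lower-closed intervals
(`[35, 47.5)` is level 3), which makes "severity >= 2.5" and "level in
{3,4,5}" coincide exactly. PTB is the percentage of active-available epochs
in levels 3-5; per-level percent times partition 100%. PTB < 30% is the
control range (the 90th percentile of controls), 30-75% intermediate,
>= 75% high. For clinician-facing reporting, PTB converts to nominal
minutes above target per 9-hour day as `max(0, PTB - 30) * 7.714`, so a
PTB of 53% is about 3 of the 9 available hours. Percent improvement after
treatment can be referenced to the control boundary rather than zero:
`referenced_improvement(63, 50, 30)` is ~39% where the raw change is ~21%.

PTD is the percentage of worn daytime epochs with DKS >= 10 (the 75th
percentile of a control population) in which neither walking nor tremor was
detected; walking contaminates the dyskinesia signal and tremor inflates
it. The published wording for the denominator ("all epochs in that
period") is ambiguous about not-worn time; counting unworn epochs would
deflate PTD in proportion to compliance, so the default denominator is
worn daytime epochs, switchable via `ptd_denominator = "all"`. The
adjusted median DKS removes walking epochs and zeroes tremor epochs whose
DKS >= 10.

## The first-dose response

The first dose reminder at or after 05:00 anchors the analysis (earlier
reminders are skipped; "at-or-after" resolves the boundary case of a
reminder at exactly 05:00). Two severities are estimated from clock-time
windows pooled across all recorded days:

* **Early-morning bradykinesia (EMB)**: the mean severity over the 5
  epochs (10 min) centred on the reminder, across days (up to 30 slot
  values on a 6-day recording). EMB is not estimable when more than half
  of the slots are unavailable. The window aggregates by mean (the source
  is silent between mean and median; the mean uses all 30 values and its
  SD is the QC quantity below).
* **Peak levodopa effect (PTE)**: severities at matching offsets from the
  dose are averaged across days (requiring at least 3 contributing days
  per offset), lightly smoothed, and the *minimum* of the smoothed curve
  between 46 and 90 minutes post-dose is taken. "Peak" effect means least
  bradykinesia; ties break to the earliest offset.

Availability for these windows means worn and not asleep; the daytime
window does not apply (the first dose usually precedes 09:00). The
inactivity mask is deliberately *not* applied here: under the default
calibration, sustained severity above level 4 is exactly what the
inactivity filter flags, so applying it would make every subject with
severe early-morning bradykinesia structurally non-estimable -- the very
phenotype the classification must detect. Early-morning unreliability is
instead handled by the excess-variability QC: a recording is excluded when
the severity SD exceeds one level at *both* anchor times (conjunctive
reading of the rule; `variability_rule = "or"` gives the stricter
disjunctive version).

The levodopa response is `Delta1 = EMB - PTE` severity, significant at
>= 1.15 levels (~14 UPDRS-III points, ~30% improvement). Wearing-off is a
rise `Delta2 >= 1` level of the smoothed curve within 2 hours after the
PTE time, truncated at the next dose reminder if that comes first.

### Smoothing the pooled curve

The inactivity mask must use the published 30-minute moving median -- that
window is part of the inactivity definition. The pooled dose-response
curve is a different object: it is already a mean over ~6 days, so its
noise SD is small, and a 30-minute median materially flattens the V-shaped
response trough, biasing both the measured response amplitude (by up to
~0.3 levels for realistic geometries) and wearing-off detection. The
package therefore smooths the pooled curve with a separate, narrower
7-epoch (14-min) moving median (`pte_smooth_window`, configurable). This
is a numerical choice, not a change to any published definition.

## Classification

Subjects passing QC with estimable EMB and PTE map to exactly one of six
classes:

| `Delta1 < 1.15` | EMB `< 2.5` | **NFC** (controlled non-fluctuator) |
| `Delta1 < 1.15` | EMB `>= 2.5` | **NFU** (uncontrolled non-fluctuator) |
| `Delta1 >= 1.15` | PTE `< 2.5` | **FC_P** / **FC_WO** by wearing-off |
| `Delta1 >= 1.15` | PTE `>= 2.5` | **FU_P** / **FU_WO** by wearing-off |

QC-excluded recordings are reported as `excluded` (written as
`excluded_variability` in summary files); missing prerequisites yield
`not_estimable`. Exclusion is applied per recording, not per subject.

## The synthetic cohort generator

`simulate_subject()` renders a 6-day, 2-minute-epoch recording from a
parametric scenario: a baseline severity; a dose-locked response that rises
linearly from 20 to 60 minutes post-dose (the peak inside the 46-90 min
search window) and either persists or decays exponentially (default
half-time 45 min, so a wearing-off response loses ~84% of its amplitude
within the 2-hour detection window); Gaussian epoch noise on the severity
scale (default SD 0.15 levels); dyskinesia at a plateau score while the
response is within 0.3 levels of its maximum (mirroring the observation
that high PTD co-occurs with controlled bradykinesia); sporadic walking
and tremor flags; scores held at 85 outside the 06:30-22:30 waking period;
and three daily dose reminders (07:00, 12:00, 17:00). Severity renders to
BKS through the inverse calibration. `scenario_library()` provides one
canonical scenario per class: non-fluctuators at baselines 1.0 and 3.5
(amplitude 0) and fluctuators with amplitudes 2.0 (from baseline 3.5,
reaching severity 1.5 at peak) and 1.5 (from baseline 4.5, reaching 3.0).
Baselines keep the flat portions of each trace below the inactivity
threshold (BKS 40 = level 4.0) except where the dose response itself
creates activity, which is what real uncontrolled recordings look like to
the mask.

Ground truth is computed from the noiseless trace with the same masks the
pipeline applies, so on noiseless scenarios the measured PTB equals the
analytic above-target fraction to within one epoch. The generator is
deterministic given its seed (base R Mersenne-Twister).

What the simulator does *not* emulate: raw accelerometry, score
autocorrelation within epochs, day-to-day dose-time jitter, missed or
unacknowledged doses, partial wear, or pharmacokinetic variation in
response latency. Passing the recovery suite therefore demonstrates that
the pipeline inverts the generative geometry it was given -- separated
classes at moderate noise -- not that it would achieve the same accuracy on
device data.

## Validation summary

The test suite checks, among others:

* the moving median against a brute-force windowed-median oracle on random
  gapped series (windows up to 31 epochs);
* hand-computed medians and percentages for every masking and scoring rule,
  including the boundary cases (BKS 80, moving median exactly 40, epoch at
  exactly 18:00, `Delta1` exactly 1.15, 15-of-30 window slots available);
* the published worked-example arithmetic: minutes conversion (53% -> ~3 h),
  referenced improvement (39% / 20.6%), treatment-change percentages,
  severity-scale equivalences (BKS 26 = level 2.5 = UPDRS 35; 1.15 levels
  ~ 14 points);
* a simulation study: on the six canonical scenarios at noise SD 0.15,
  class recovery over 100 seeds per scenario with mean absolute `Delta1`
  error, and noiseless PTB against the analytic fraction. The same study,
  at 40 seeds per scenario, is what `scripts/acceptance.R` reports.

Problem sizes (6-day recordings, 100 seeds per scenario in the test suite,
40 in the acceptance script) were chosen to give stable recovery estimates
while keeping a full run fast on a single CPU.

## Known limitations

* The severity calibration between its anchors is linear by assumption;
  only the target-boundary anchor is externally fixed.
* Only the first dose of the day is analysed; wearing-off after later doses
  (or slower than 2 h after peak) is not detected.
* The excess-variability rule and the EMB availability rule act per
  recording; cohort-level exclusion fractions will depend on wear
  compliance in ways the simulator does not model.
* Walking and tremor arrive as input flags; their detectors are outside
  scope.
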