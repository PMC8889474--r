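---
title: "Eye-metric analysis of VR nicotine cue-exposure sessions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eye-metric analysis of VR nicotine cue-exposure sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrcue)
```

## The measurement problem

Cue-exposure paradigms in virtual reality present a participant with scenes
that either do ("Active") or do not ("Neutral") contain nicotine and tobacco
product cues, while a headset-integrated eye tracker records a 100 Hz
timeseries (gaze intersection point, head pose, per-eye pupil diameter and
eye openness) plus an event stream (gaze-object switches, blinks, controller
buttons, post-scene surveys). From these logs, three candidate objective
correlates of craving are derived:

* **Attentional bias** — cumulative gaze dwell on Active-category versus
  Neutral-category objects, in milliseconds;
* **Pupillometry** — mean pupil diameter while fixating each cue category,
  in millimeters;
* **Spontaneous eye-blink rate (EBR)** — blinks per minute, a proposed
  non-invasive proxy for striatal dopaminergic tone.

`vrcue` implements the full extraction and analysis chain for such logs, and
a synthetic session generator with recorded ground truth so that every stage
can be validated without hardware.

## Blink detection from pupil dropout

The tracker reports a missing pupil diameter when the eyelid covers the
pupil, so maximal contiguous runs of missing samples are treated as eye
closure candidates. A candidate is kept as a blink when its duration lies in
[50, 500] ms, inclusive on both ends: shorter runs are discarded as tracker
noise, longer runs as microsleeps (the discard rules are strict
inequalities, so 50 ms and 500 ms runs count). Durations are run length
times the 10 ms sampling period. Runs truncated by the end of a scene have
undefined duration and are tallied separately rather than classified.

Two candidate definitions are provided. The default, `BOTH_EYES`, requires
both pupils missing at a tick — complete closure is binocular, and it makes
the detector robust to single-eye tracker dropouts. `EITHER_EYE` treats any
missing eye as a candidate tick; the two modes differ exactly on monocular
dropout runs, and both are surfaced so their effect on EBR can be compared.
EBR is the blink count divided by the scene duration in minutes, exactly;
counts in roughly 12–40 blinks/min are the physiologically plausible range.

## Fixation accounting and attentional bias

The fixation unit is the object-switch interval, not a velocity-parsed
saccade event: a gaze switch to object *o* at time *t* contributes
*t*~next~ − *t* milliseconds to *o*'s cumulative dwell, where *t*~next~ is
the next switch or the scene end. Dwell accumulates per object inside four
category dictionaries — Active, Neutral, Miscellaneous, Background. Total
fixation indices sum a category's objects; mean indices divide the total by
the number of distinct objects gazed (a category never gazed has an absent
mean, not zero). Time before the first switch belongs to no object, so
category totals plus that uncovered time tile the scene exactly — a
conservation property the tests assert.

The attentional-bias score is the mean over the three Active scenes of the
per-scene difference (Active total − Neutral total), in milliseconds — a
difference rather than a ratio, matching how such bias is reported on a
millisecond axis. Scene contrasts use the two cue categories only;
Miscellaneous and Background dwell is excluded from Active-vs-Neutral
comparisons. Whether "neutral cue" dwell should absorb Miscellaneous objects
is genuinely open; excluding them is the stricter reading and is flagged for
sensitivity analysis.

## Pupillometry

Per sample, the diameter is the mean of the available eyes (binocular mean
when both present, the present eye's value otherwise). Samples inside any
missing-run candidate — blink, noise dropout or microsleep — are excluded,
optionally widened by a `margin_ms` guard for lid-occlusion artifacts near
blinks (default 0: exclude exactly the missing runs). Each remaining sample
contributes to the category of the object gazed at that tick, and raw
millimeter means are reported per scene and category, weighted per sample.
No baseline correction or luminance model is applied.

## Gaze-to-object mapping

Commercial VR eye trackers ship learned object-selection algorithms that are
not reproducible. `vrcue` provides a documented angular-proximity selector
instead: the selected object minimises the angle between the gaze direction
and the eye-to-object vector, gated at the larger of a fixed threshold
(default 3°, a typical tracker accuracy bound) and the angular radius
subtended by the object's selection sphere, so large objects remain
selectable at grazing angles. Ties break by distance, then name, making the
selector fully deterministic. A manipulation *lock* overrides geometry:
while a participant holds an object, that object is the selection until
release. Tests verify lock dominance and equivalence with an exhaustive
angular scan on random poses.

## Paired contrasts and effect sizes

Every condition contrast is a two-tailed paired-samples *t* test. The effect
size is the paired *d~z~* = mean difference / SD of differences, which
equals *t*/√*n*; the implementation enforces this identity exactly. 95%
confidence intervals use the normal-approximation standard error
√(1/*n* + *d*²/2*n*), applied to *d* rounded to two decimals — this
convention reproduces published pilot intervals that the unrounded *d* does
not, and where the published rounding drifts, the reconstruction stays
within one unit in the second decimal. Exact noncentral-*t* intervals are
deliberately not used: available formulas disagree with the reported values.
Participants missing either member of a pair are dropped per contrast
(pairwise deletion), so degrees of freedom vary across rows of one battery,
as they do in real cohorts with partial technical failures. No
multiple-testing correction is applied by default; `holm = TRUE` appends
Holm-adjusted p-values.

Exploratory associations (attentional bias, pupil difference and EBR against
in-task craving and past-90-day use episodes) are Pearson correlations.

## The synthetic session generator

`sim_config()` defines the generating conditions; `simulate_participant()`
returns both a log and the ground truth that produced it. What it emulates:

* **Gaze** is a continuous-time switch process: dwell durations are
  exponential with mean `mean_dwell_ms` (default 1200 ms, a typical
  free-viewing dwell), truncated at 10 s; the next object is drawn with
  probability proportional to its attractiveness weight, with
  Active-category weights scaled by `dwell_bias` (default 2, matching the
  roughly 2:1 Active:Neutral dwell seen in cue-rich patio/barbecue scenes).
  Draws are independent with replacement and consecutive repeats merge, so
  each object's long-run time share is exactly proportional to its weight —
  that choice is what makes `dwell_bias` identifiable as the Active:Neutral
  time ratio (forbidding self-transitions would distort the ratio by several
  percent at these catalog sizes).
* **Pupil diameter** is a participant baseline (normal, mean 3.97 mm — the
  neutral-cue pilot mean — SD 0.7 mm) plus an additive shift
  `pupil_cue_delta_mm` while gazing Active-category objects (default
  −0.10 mm, the pooled Active-minus-Neutral pilot difference) plus per-eye
  Gaussian noise (SD 0.30 mm).
* **Blinks** are Poisson at `blink_rate_per_min` (default 20, the centre of
  the plausibility band) with mean-preserving lognormal between-participant
  spread (`blink_rate_sdlog` 0.25, a ~25% coefficient of variation chosen so
  that well over 90% of simulated scenes fall inside 12–40 blinks/min);
  durations are uniform on [50, 500] ms. Microsleeps (default 0.3/min,
  600–2000 ms) and single-eye tracker dropouts (default 6/min, 10–40 ms)
  straddle the detector's discard thresholds. Counts are drawn first and
  intervals then placed by uniform gap insertion with a one-tick guard, so
  realized counts are exactly Poisson, closures never merge, and no run
  touches the scene end — which is what lets the recovery tests demand exact
  onset/duration agreement between detector and ground truth.
* **Surveys** are truncated normals on [0, 100], rounded to integers: a
  participant-level craving latent (SD 18) shared across scenes plus
  scene-type means (defaults 42.77 Active / 29.42 Neutral, the pilot means)
  and scene noise (SD 20). Truncation at 0 pulls realized means slightly
  above low latent means; the recovery test therefore checks cohort means
  against the numerically integrated truncated-normal expectation rather
  than the latent values. The latent SDs are modeling choices: published
  pilot dispersions describe scene-averaged, skewed, truncated ratings and
  cannot be plugged in as latent parameters.
* **Use episodes** (past 90 days) are lognormal with meanlog 6.152 and sdlog
  0.997, matching a heavily right-skewed sample (mean ≈ 772, SD ≈ 1008);
  `use_episodes_slope` couples episodes linearly to a participant's dwell
  bias so bias–use correlations can be generated at will.
* The **driving-reversal preset** (`driving_reversal = TRUE`, on in
  `preset_paper()`) recategorises the Driving scene's large street-video
  panel as a Neutral cue with high attractiveness, reproducing the observed
  sign reversal of attentional bias in driving-style scenes where an
  engaging background video competes with the product cues.

What it does **not** emulate: saccade kinematics and microsaccades, the
pupillary light reflex and luminance coupling, head movement, blink-adjacent
partial occlusion artifacts, object manipulation (no button events are
generated), and any dependence of craving on scene order or time. Absolute dwell
shares are stylized — background panels absorb most dwell (attractiveness
20 versus 1 for hand objects), but cue objects still receive more dwell
than in real scenes; only the Active:Neutral ratio is calibrated. Passing
tests therefore demonstrate that the pipeline measures what the generator
encodes — not that real tracker data are this clean; real logs will need the
`margin_ms` guard and plausibility checks more than the synthetic ones do.

Determinism: every draw descends from `(seed, participant_index)` through a
modular substream hash, so a participant's log is byte-identical across runs
and unaffected by cohort size.

## Numerical and design choices

* Timestamps are integer scene-relative milliseconds; the on-disk
  missing-value sentinel is −1.0 (readers also accept empty/null), matching
  common tracker-SDK conventions. Whether upstream timestamps are scene- or
  session-relative is unspecified in the source logs this format mirrors;
  scene-relative is used throughout.
* Coordinates are right-handed meters, y up, with the headset near the
  origin at 1.6 m eye height.
* Candidate classification at exactly 50/500 ms is inclusive (blink);
  truncated runs are counted, never classified.
* The gaze selector's tie-break (angle, then distance, then name) exists
  purely for determinism; ties are measure-zero in practice.
* `paired_contrast` refuses fewer than 3 complete pairs and zero-variance
  differences rather than returning degenerate statistics.
* Empty categories propagate as absent (`NA`) means, never as zeros; the
  bias difference uses a zero total for an un-gazed category, which is the
  correct limit of "no dwell".

## Problem sizes used by the validation suite

The shipped tests run, on one CPU, with sizes chosen as a compromise between
statistical resolution and runtime: oracle equivalence on 500 random blink
traces and 300 random event sequences; parameter recovery (dwell bias, pupil
shift, blink rate) over 100 independent 60 s scenes each, judged at ±3
standard errors; null calibration over 500 cohorts of 12 participants with
20 s scenes, giving 2000 null p-values for the uniformity (Kolmogorov–
Smirnov) and type-I-error checks; and band calibration over 120 full-length
(5 min) scenes. Scene duration only scales the precision of per-scene
estimates, not the estimands, so short scenes are used wherever a test needs
many replicates.

## Known limitations

* The angular-proximity selector is a stand-in for proprietary learned
  selection; on real data, reprocessing raw gaze through it will not
  reproduce the vendor's object choices near small, fast-moving objects.
* The EBR candidate unit (binocular vs per-eye) is genuinely ambiguous in
  the field; both modes are implemented and the default (`BOTH_EYES`) is a
  documented choice, not an established standard.
* Questionnaire scoring implements only the linear averaging rule onto
  0–100; instrument item maps (presence and sickness subscales) must be
  supplied by the user.
* The d~z~ confidence interval is a normal approximation computed from the
  rounded effect size; it matches reporting practice but is not an exact
  interval.
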