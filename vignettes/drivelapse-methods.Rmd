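---
title: "Measuring sustained attention from continuous lane-keeping performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sustained attention from continuous lane-keeping performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivelapse)
```

## The task and the measurement model

Classic computerized attention tests (continuous performance tests in the
go/no-go family) observe a participant only at discrete stimulus onsets. A
continuously recorded driving task observes them at every instant: the
participant steers a car along a road of curves and straights, the car is
pulled toward the outside of every curve, and the signed lateral distance
from the road centerline is recorded at 50 Hz. Lapses of attention have an
immediate kinematic signature — the uncorrected car drifts outward and pins
against the road edge — so the error trace localises *when* attention was
lost and recovered, not just *how much* error accumulated.

`drivelapse` implements this measurement chain end to end: a 1-D simulator
of the task, synthetic driver cohorts to stand in for participants,
session/cohort file formats, and the three analysis stages — age-stratified
boxplot statistics, k-means clustering of error trajectories, and the
fence/sustained-run attention procedure.

## Task kinematics

The analysis never needs 2-D world coordinates, so the simulator is the
minimal kinematic model of the lateral state:

* A held arrow key moves the car laterally at `lateral_speed` = 10 m/s.
* On curves the car drifts toward the outside of the curve at
  `curve_drift_ratio` = 0.45 of the key speed (4.5 m/s). The stated force
  has velocity units, so the model is kinematic — velocities, not
  accelerations.
* The position is clamped to `[-half_width, half_width]`; engaging the clamp
  is a collision with the road edge. The road half-width is not part of the
  task description; the default of 3.0 m is chosen so that published-scale
  non-outlier intervals (upper fences around 2.6 m for 11-year-olds) leave
  attainable positions beyond the fence, which the outlier analysis
  requires.
* Integration is explicit Euler at the sampling tick (dt = 1/50 s); the
  dynamics and the recording share one clock. At 10 m/s over a 3 m
  half-road, 50 Hz resolves every excursion to 0.2 m per tick.

The test circuit has 58 curves and 58 straights of equal duration, laid out
alternately starting with a straight; curve handedness is drawn 50/50 from a
seed, because handedness only flips the sign of the drift and no canonical
sequence exists. A session records exactly 34,496 samples (689.92 s). The
segment duration is defined as `34496 / 50 / 116` ≈ 5.9476 s so that the
sample count — the quantity the analysis depends on — tiles the circuit
exactly; a nominal "11.5 min" circuit would need 34,500 samples, and the
fixed sample count wins that conflict. The 40-second tutorial circuit (4
curves, 4 straights) keeps 5 s segments.

## The synthetic cohort

No recordings of real participants are distributed, so the package generates
a synthetic cohort whose *statistical structure* matches what the analysis
assumes. Each driver is a small feedback controller:

* **reaction delay** — the key decision at time *t* uses the position
  observed `reaction_delay` seconds earlier;
* **deadband** — no correction while the observed |position| is at or below
  `deadband` meters;
* **motor noise** — each tick, with probability `miskey_prob`, the chosen
  key is replaced by a uniformly random one;
* **lapse schedule** — during scheduled inattentive intervals the driver
  presses nothing and the car is carried by the curve drift alone (the
  simplest, parameter-free lapse model: drift-to-edge reproduces the large
  sustained deviations the procedure must detect).

Skill improves linearly with age: reaction delay `0.22 − 0.02 (age − 7)` s,
deadband `0.35 − 0.015 (age − 7)` m, miskey probability
`0.02 − 0.0015 (age − 7)` per tick. The slopes were fixed once, at design
time, by three requirements: (i) each age from 7 to 17 maps to a distinct
delay in whole samples at 50 Hz, so pooled error medians decrease
monotonically with age (the younger-worse gradient); (ii) an attentive
11-year-old group's pooled signed positions give Tukey fences well inside
the ±3 m road (about [−2.8, 2.7]), on the scale of published reference
intervals; and (iii) a lapsed driver's edge-pinned positions (±3 m) lie
outside any such group's fences, so lapses are detectable. These parameter
values are a modeling choice, not an estimate from data: no claim is made
that children implement a delayed deadband controller. Passing tests show
the *procedure* recovers planted ground truth under this model; they cannot
validate the model against real driving.

Four archetypes parameterise the lapse schedules, mirroring the qualitative
patterns such cohorts show: `uniform_good` (no lapses), `uniform_poor` (one
lapse covering the session), `onset_loss` (attentive until an onset time,
default drawn uniformly between 17% and 70% of the session, then inattentive
to the end), and `alternating` (exponentially distributed attentive stretches
of mean 120 s and inattentive stretches of mean 60 s). The default cohort
mix is 75/8/9/8 percent respectively — a majority of unremarkable
performers with a minority of each deviant pattern — over 63 participants
aged 7–17 (uniform over integer ages; the generator does not attempt to
match any particular cohort's exact age moments).

Every stochastic step is a pure function of a seed: cohort-level draws from
the master seed, one documented RNG stream per session (miskey variates
first, then replacement keys), so any session or cohort regenerates
bit-identically.

## Error statistics

The error at each instant is the absolute lateral position. Per age, the
positions of all participants of that age are pooled and summarised by
Tukey boxplot statistics: quartiles by linear interpolation of order
statistics (`quantile` type 7 — the convention is recorded in every output
because the fences depend on it), IQR, and fences at Q1 − 1.5·IQR and
Q3 + 1.5·IQR. Observations strictly outside the fences are outliers;
values exactly on a fence are not.

Two pooling modes exist because they answer different questions: absolute
error for the age-gradient boxplots, and *signed* positions for the
attention fences — a group's non-outlier interval need not be symmetric
around the centerline, and asymmetric reference intervals like [−2.4, 2.6]
only arise on signed data.

## The attention procedure

For a chosen participant:

1. Fences are computed from the pooled signed positions of their age group.
   The analyzed participant is included in the pool by default (the
   reference interval describes "all children of that age"); a
   `leave_one_out` flag exposes the alternative for sensitivity analysis.
2. Each sample is flagged outlying or not against the fences.
3. Maximal stretches of consecutive outlying samples lasting **one second
   or more** (≥ 50 samples at 50 Hz, inclusive) are sustained errors;
   shorter excursions are instantaneous slips and are discarded. The 1 s
   threshold is a task-level operating point, exposed as `min_duration_s`.
4. The profile reports the first sustained-error onset (the operational
   attention span), every loss/recovery interval as half-open 0-based
   sample indices, the total inattentive time, and whether attention was
   maintained to the end.

Run boundaries are half-open `[start, end)`: `end` is the first non-outlying
observation after the run, i.e. the recovery observation. Durations are
always computed from the indices — `(end − start) / 50` seconds — and times
from `index / 50 / 60` minutes. Two sustained runs separated by *any*
attentive gap remain distinct; no gap-bridging rule is applied.

A degenerate age group whose pooled IQR is zero collapses the fences to a
point; this is flagged with a warning (not an error) because every nonzero
deviation then counts as outlying.

**Known sensitivity.** When the analyzed deviant is a large fraction of a
small age group, their own edge-pinned samples widen the pooled IQR and can
push one fence past the road half-width; a lapse that pins the car on that
side is then detected only when a later opposite-handed curve drags the car
across the other fence, delaying the measured onset by up to a few road
segments. Larger (or leave-one-out) reference pools avoid this; the package
deliberately reproduces the include-the-participant convention by default.

## Clustering of error trajectories

Participants of one age are clustered on their binned error trajectory: the
mean absolute error over consecutive 10 s bins (68 features for a full
session; a trailing partial bin is dropped). Binning preserves the temporal
patterns that distinguish the archetypes while avoiding distances on raw
34,496-sample vectors; features share units (meters), so no per-feature
normalisation is applied. The representation is a documented choice — the
analysis tradition this follows states only that participants are
classified "according to their errors".

`kmeans_fit` runs Lloyd iterations (via `stats::kmeans`) from k-means++
seedings, keeping the best of 10 restarts; `scree` additionally initialises
each k from the (k−1) solution's centers plus the point farthest from its
center, which guarantees a non-increasing inertia curve. The number of
clusters is picked from the scree table by an explicit elbow rule — the
interior k maximising the second difference
`(W(k−1) − W(k)) − (W(k) − W(k+1))`, ties toward smaller k — replacing the
visual scree-plot judgement with a testable criterion; the scree table is
always emitted for human inspection. Singleton clusters are reported by
participant id, since isolating one aberrant child is a result of interest
in its own right. With all-identical trajectories every inertia is ~0, all
elbow scores tie, and the rule returns k = 2 with a `no_structure` flag.

Small-scale checks compare the best-of-restarts inertia against exhaustive
enumeration of all partitions (n ≤ 8), and cluster agreement is always
evaluated by pair-counting, never by raw label identity.

## Problem sizes and verification

The test suite and the acceptance script regenerate everything they check:
full-length sessions (34,496 samples) wherever the contract demands it, and
2,000–5,000-sample sessions on proportionally shorter circuits for
behavior-level properties, chosen to exercise identical code paths at lower
cost. Verification batches are: 1,000 random masks against a brute-force
run-scan, 1,000 random samples against a sort-and-interpolate quantile
oracle, 10,000 random-policy dynamics steps against closed forms, 20-seed
recovery batches for the planted-lapse onset (±2 s), planted cluster counts
(3 archetypes), and singleton isolation, and a 63-participant cohort for
the age gradient (Spearman ρ < 0 between age and median absolute error).

## Limitations

* The driver model is a stand-in, not a fitted model of children's steering;
  only the analysis procedures, not the cohort realism, are validated here.
* Onset localisation inherits the fence-contamination sensitivity described
  above for small reference groups.
* No hyperactivity/impulsivity measures (key-press dynamics) are derived,
  and no inferential statistics across ages are computed — the pipeline is
  descriptive, as is the analysis tradition it implements.
* The elbow rule is one defensible formalisation of scree-plot judgement;
  on inertia curves with a single dominant drop it prefers k = 2 even when
  finer structure exists, which is why the scree table is always written
  alongside the selection.
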