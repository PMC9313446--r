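# drivelapse

Sustained-attention assessment from continuous lane-keeping performance.

Discrete-stimulus attention tests (the go/no-go family of continuous
performance tests) sample a participant's behavior only at stimulus onsets.
A continuously recorded driving task observes it at every instant: the
participant steers a car along a circuit of curves and straights at constant
forward speed, every curve pulls the car toward its outside, and the signed
lateral distance from the road centerline is logged at 50 Hz (34,496
samples, about 11.5 min). Because an unattended car drifts to the road edge
within a second, the error trace localises *when* attention is lost and
recovered — information a summary error score throws away.

`drivelapse` is aimed at researchers developing or evaluating such
continuous behavioral measures. It implements the full chain:

* **Task simulator** — 1-D lateral kinematics: key speed 10 m/s, outward
  curve drift 0.45 × 10 m/s, position clamped to the ±3 m road half-width
  (clamping = collision with the edge), explicit Euler at the 50 Hz tick.
* **Synthetic cohorts** — closed-loop driver models (reaction delay,
  deadband, motor noise) with scheduled attention lapses; four behavioral
  archetypes (uniformly good, uniformly poor, attention lost from an onset
  time, alternating) and an age–skill gradient over ages 7–17.
* **Session I/O** — plain-CSV session recordings with `#`-comment metadata
  and a cohort manifest; byte-stable round trips.
* **Error statistics** — per-age pooled boxplot statistics of the absolute
  error `|position|`: type-7 quartiles, IQR, Tukey fences
  `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`, outlier counts.
* **Attention procedure** — fences from the pooled *signed* positions of
  the participant's age group; samples strictly outside the fences are
  outliers; maximal outlier runs lasting ≥ 1 s are **sustained errors**;
  the first one marks the operational attention span, and each run's
  half-open `[start, end)` observation window gives loss and recovery
  times.
* **Trajectory clustering** — k-means (k-means++ seeding, best-of-restarts
  Lloyd, nested initialisation for a monotone scree) on 10 s-binned mean
  absolute error, with an explicit elbow rule: the interior k maximising
  the second difference of the inertia curve.

## Worked example

Simulate an age-11 group of seven attentive drivers plus one who stops
attending at 412.34 s (observation 20,617), then run the analysis:

```r
library(drivelapse)

trk <- build_track(curve_direction_seed = 42)   # 58 curves + 58 straights
dur <- 34496 / 50                               # session length, s
sessions <- lapply(1:8, function(i) {
  sched <- if (i == 8) lapse_schedule(list(c(412.34, dur))) else lapse_schedule()
  simulate_session(trk, default_profile_for_age(11, lapse_schedule = sched),
                   seed = 100 + i, participant_id = sprintf("11-%d", i), age = 11)
})
co <- cohort(sessions, archetype = c(rep("uniform_good", 7), "onset_loss"))

round(age_boxplot_table(co), 3)
#>   age      n   q1 median   q3  iqr lower_fence upper_fence outlier_count
#> 1  11 275968 0.32   0.72 1.18 0.86       -0.97        2.47         13256

prof <- compute_attention(co, "11-8")
round(attr(prof, "fences"), 2)
#> lower upper
#> -2.93  2.75
prof
#> <attention_profile> 11-8: 12 sustained run(s)
#>   first loss at 6.88 min (observation 20638)
#>   total inattentive time 263.30 s (4.39 min)
#>   attentive to end of task: FALSE

cluster_age_group(co, 11, seed = 1)
#> <cluster_result> age 11: k = 2 selected from scree over k = 1..6
#>   cluster 1: 11-1, 11-2, 11-3, 11-4, 11-5, 11-6, 11-7
#>   cluster 2: 11-8
```

The age group's non-outlier interval is [−2.93, 2.75] m. The planted lapse
at observation 20,617 is picked up 21 samples (0.42 s) later, once the
drifting car crosses the fence and stays outside for a second; the first
sustained error at 6.88 min is the participant's measured attention span,
and k-means isolates the same participant as a singleton cluster. (After
the lapse the car pins alternately at the two road edges, crossing the
interior between curves, so one long lapse appears as several sustained
runs.) `worked_example()` prints the reference single-run narrative —
attention lost at observation 20,617 (6.87 min) and recovered at
observation 31,008 — from a constructed session.

`analyze_cohort(cohort, out_dir)` runs everything over a cohort and writes
the boxplot table, per-age scree tables and cluster assignments, one
attention JSON per participant, and figures (age boxplots, error-over-time,
scree, and a per-participant triptych: group boxplot, outlier-marked
trajectory, sustained-error trajectory). A thin command-line front end is
installed as `exec/drivelapse` (subcommands `simulate`, `analyze`,
`worked-example`).

## File formats

Session CSV: `#`-prefixed metadata lines (`participant_id`, `age`,
`sample_rate`, compact JSON `config`), then
`index,t,position,road_direction,key,collision` with `t` and `position` at
fixed 6-decimal precision, `road_direction` ∈ {S, L, R}, `key` ∈
{left, right, none}, `collision` ∈ {0, 1}. Cohort manifest CSV:
`participant_id, age, archetype, seed, session_file` (paths relative to the
manifest). Tracks serialize to JSON. Writing a file read back with
`read_session()` reproduces it byte-for-byte.

See the methods vignette (`vignettes/drivelapse-methods.Rmd`) for the
modeling decisions, parameter defaults and known limitations.
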