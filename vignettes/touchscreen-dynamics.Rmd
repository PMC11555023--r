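---
title: "Methods: joint interval distributions and cluster-based permutation inference for touchscreen dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint interval distributions and cluster-based permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapjid)
```

## The problem

Smartphone touchscreen interactions form a high-resolution behavioural time
series that can be collected passively over months. In people with epilepsy,
changes in anti-seizure medication (ASM) load and the occurrence of
convulsive seizures are hypothesised to leave signatures in the *rhythm* of
interactions — not in how much the phone is used, but in how quickly one
touch follows another. `tapjid` implements a complete analysis pipeline for
a single subject observed over a long study with three periods (before,
during and after an ASM taper) and a single convulsion day:

1. segment the continuous tap stream into behavioural days,
2. summarise each day as a **joint interval distribution** (JID),
3. compare groups of daily JIDs with a **cluster-based permutation test**,
4. contrast the convulsion day against the average of the preceding days.

Because raw single-subject streams of this kind are not publicly
distributable, the package ships a fully parameterised synthetic generator
that emulates the statistical structure the analysis assumes, so every
stage is testable end to end.

## The joint interval distribution

Let $t_1 < t_2 < \dots$ be tap timestamps and $x_k = t_{k+1} - t_k$ the
inter-touch intervals (ITIs), in seconds. Each consecutive ITI pair
$(x_k, x_{k+1})$ is a point in a 2D space after a $\log_{10}$ transform.
The JID of a day is the smoothed, discretised distribution of these points:
an isotropic Gaussian kernel of standard deviation $h = 0.1$ (in
$\log_{10}$ units) is centred on each pair, the mean over pairs is
evaluated at the centres of a $50 \times 50$ grid spanning
$[\log_{10} 0.03,\, \log_{10} 100]$ — approximately 30 ms to 100 s — and
the result is renormalised. Row/column 1 is the fastest bin, so the
lower-left corner of the matrix captures fast consecutive interactions
("fast–fast"), the upper-right slow ones, and the diagonal rhythmic
activity.

Choices that the method's verbal description leaves open, fixed here:

* **Evaluation at bin centres**, not integration over bins. This keeps an
  exact analytic oracle (a single pair must reproduce the discretised
  product Gaussian bin for bin) and differs from bin integration by
  $O(w^2)$ with bin width $w \approx 0.0705$.
* **Bandwidth** means the kernel standard deviation per axis, isotropic,
  no cross-term.
* **Normalisation** defaults to *probability mass* (entries sum to 1).
  Per-day unit mass removes the daily-volume confound from the bin-wise
  t-tests, which are scale sensitive. A *density* mode (unit integral over
  log-area) is available.
* **Out-of-range pairs** are not clipped: kernels are evaluated where the
  pair lies and mass outside the grid is simply lost before
  renormalisation. The per-day fraction of out-of-grid pairs is recorded on
  the object (`out_of_grid`). With the default generator ~1% of mass sits
  beyond the 100 s edge.
* **No boundary correction** at the grid edges.

`average_jid()` is the unweighted element-wise mean (used for
period-average maps and the convulsion-day baseline), and
`jid_difference()` the element-wise difference, which sums to zero for
probability-mass inputs — a conservation law the tests assert to $10^{-9}$.

## Cluster-based permutation inference

Comparing two periods bin-wise means 2500 simultaneous t-tests. The package
controls this family with max-cluster-size permutation inference:

1. compute a two-sample t statistic per bin (pooled variance by default,
   $\mathrm{df} = n_a + n_b - 2$; Welch available),
2. threshold at the two-sided critical value for the cluster-forming level
   $p < 0.01$,
3. group supra-threshold bins into connected components, positive and
   negative signs separately (4-neighbour connectivity by default,
   8-neighbour available),
4. repeat steps 1–3 under $B = 1000$ random reassignments of the day
   labels (group sizes preserved), recording the maximal cluster size over
   both signs each time,
5. declare an observed cluster significant when its size exceeds the 95th
   percentile of that null distribution, and report per-cluster
   $p = (1 + \#\{\text{null max} \ge \text{size}\})/(B + 1)$.

Details fixed by the package where the method description is silent:
pooling the two signs into one null maximum controls the two-sided family;
the $+1$ p-value correction keeps p strictly positive; permutations are
drawn without deduplication (collisions are immaterial at $B = 1000$), with
an exhaustive mode that enumerates all label splits for small groups; bins
with zero variance in both groups (the empty JID corners) are set to
$t = 0$, flagged, and never enter clusters. Swapping the two groups negates
the t-map and, in exhaustive mode, leaves every cluster size and p-value
identical — a symmetry the tests check exactly.

The single-day convulsion contrast is purely descriptive: the convulsion
day's JID minus the average of the three preceding days, summarised as
signed mass by quadrant (grid midpoint split; a reporting convention). With
$n = 1$ there is no valid day-level permutation, so no test is offered for
it.

## Day segmentation

The pipeline needs stable behavioural days, bounded by rise times, so that
no ITI spans a night. Dedicated sleep/wake detection from device usage is a
research topic of its own; the package uses a documented gap heuristic that
delivers the one property the analysis needs — a stable partition:

* within each noon-to-noon window, consider event gaps of at least
  `min_sleep_gap` (default 3 h) whose **end lies inside that window** and
  whose end clock-time falls in the search window (default 20:00–12:00);
* the longest such gap is the night's sleep and its end the rise time;
* the stream's first event opens the first day; days are half-open
  rise-to-rise intervals $[r_i, r_{i+1})$.

Requiring the gap end (rather than any overlap) to lie inside the window
assigns each night gap to exactly one window; an overlap rule lets a single
long gap claim two windows whenever a light day ends before noon, silently
merging days. Windows with no qualifying gap raise a merge warning. Days
with fewer than `min_day_events` (default 30) events are kept but flagged,
and flagged days are excluded from group statistics by the pipeline.
Against the generator's ground-truth wake times, detected rise times land
within 30 minutes on ≥ 95% of days.

## The synthetic study generator

`synth_config()` encodes the study conditions the pipeline is designed
for: periods of 82 / 12 / 91 days (pre-taper / taper / post-taper), one
convulsion day inside the taper period (default: three-quarters of the way
through it), and a daily interaction volume with median ≈ 3311 and IQR ≈
2531–4766. Daily counts follow a rounded log-normal law; its parameters
(`meanlog = log(3311)`, `sdlog = 0.47`) were fixed once by simulating the
full generator — including nightly truncation — against the median/IQR
targets, giving simulated median 3316 and IQR 2400–4506.

Within a day, $\log_{10}$ ITIs follow a two-component normal mixture:
a *fast* burst component (weight 0.60, mean $-0.45$, sd 0.35 — about
0.35 s) and a *slow* pause component (weight 0.40, mean 1.15, sd 0.45 —
about 14 s). Consecutive intervals are coupled by a first-order
autoregressive Gaussian copula (`pair_correlation`, default 0.3): a
stationary AR(1) latent normal series is mapped through the mixture
quantile function, so the marginal stays exactly the mixture while
consecutive pairs carry rank correlation ≈ 0.3 and the JID acquires
non-product joint structure. Two further pieces of realism:

* `day_weight_sd` (default 0.04) jitters the fast-component weight day by
  day, so between-day JID variance is behavioural, not just sampling noise;
* events are emitted from a jittered rise time (default 07:30 ± 20 min)
  and truncated at the jittered sleep-window start (default 23:30), so
  heavy days end early rather than run through the night.

Condition effects are weight shifts between the two components: tapering
days move 0.15 of the weight from slow to fast (accelerated next-interval
dynamics); the convulsion day moves 0.30 from fast to slow. These
magnitudes are free parameters of the generator — chosen so the effects are
clearly detectable at study scale — not estimates of any real effect size.

What the generator does **not** emulate: app or content structure,
screen-on sessions, multi-device use, weekly rhythms, drift in daily
volume, or focal seizures without convulsion. Passing tests therefore
demonstrate that the pipeline recovers effects of this kind and calibrates
correctly under this null — not that real data carry such effects.

## Numerical and validation choices

* Kernel evaluation is vectorised as two $50 \times n$ Gaussian design
  matrices and one matrix product; a brute-force per-pair double loop is
  the test oracle (agreement to $10^{-10}$ for ≤ 20 pairs).
* Connected components use a stack-based flood fill; an independent
  igraph-based labelling is the oracle on 1000 random masks.
* The permutation loop computes all t-maps for a block of permutations with
  three matrix products (group sums and sums of squares against a 0/1
  assignment matrix); block size is a memory knob with no effect on
  results. One-pass variances are clamped at zero against cancellation.
* The 95th percentile of the integer null sizes uses R's default quantile
  definition (type 7); significance is *strictly greater than* the
  threshold.
* Reproducibility: every generator day derives its own seed from the study
  seed and day index; the permutation draw is seeded explicitly; two runs
  of `run_full_pipeline()` from the same config are file-identical.

Validation problem sizes (chosen to keep the full suite within minutes on
one CPU): type-I calibration uses 500 replicates of 20-vs-20 null studies
with $B = 200$ and 800 interactions/day; effect recovery uses 100
replicates of the full 82/12/91 design with $B = 200$ and the same daily
volume (pilot runs showed calibration and power are insensitive to the
volume reduction); the convulsion-day contrast uses 100 replicates at
default volumes. Calibration lands in $[0.03, 0.07]$; a significant
fast–fast cluster appears in ≥ 80% of tapering replicates with the
post-restart sign reversal; the convulsion-day contrast puts net mass in
the slow–slow quadrant in ≥ 95% of replicates.

## Limitations

* The rise-time heuristic is validated against the generator's ground
  truth, not against polysomnography or the dedicated detection literature;
  shift workers or fragmented sleep would defeat the single-night-gap
  assumption.
* Single-subject inference: permutation is over days, so significant
  clusters generalise to this subject's days, not to a population.
* The convulsion-day contrast is descriptive; with one event day there is
  no severity-matched null.
* KDE bin-centre evaluation slightly under-weights mass near the grid
  edges relative to bin integration; both groups share the bias, so
  contrasts are unaffected to first order.

## A worked run

```{r example, eval = FALSE}
cfg <- synth_config(seed = 42)
study <- generate_study(cfg)
summarize_study(study)

stream <- study_stream(study)
days <- split_days(stream, detect_rise_times(stream))
jids <- daily_jids(days)
design <- design_from_study(study)

tt <- run_transition_tests(jids, design, B = 1000, seed = 42)
tt
run_seizure_contrast(jids, design)
```

The README shows this run's printed output. The same analysis is available
from a YAML config through `run_full_pipeline()`, which also writes every
intermediate artifact (tap CSV, segmentation report, per-day JID files,
serialised test results, run manifest) to disk.
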