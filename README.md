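# tapjid

Joint interval distributions and cluster-based permutation tests for
smartphone touchscreen dynamics.

## What it is for

Passively recorded touchscreen tap timestamps are a months-long behavioural
time series. In a person with epilepsy, changes in anti-seizure medication
(ASM) load and the day of a convulsive seizure are expected to change the
*rhythm* of phone use — the joint structure of consecutive inter-touch
intervals — rather than its volume. `tapjid` is for researchers analysing
such single-subject streams: it segments a raw timestamp stream into
behavioural days, summarises each day as a joint interval distribution, and
tests period contrasts nonparametrically.

## The method

For tap times $t_1 < t_2 < \dots$ and inter-touch intervals
$x_k = t_{k+1} - t_k$ (seconds), each day's **joint interval distribution
(JID)** is a 2D Gaussian kernel density (bandwidth 0.1 in $\log_{10}$
units) of the consecutive pairs $(\log_{10} x_k,\ \log_{10} x_{k+1})$,
discretised on a $50 \times 50$ grid from about 30 ms to 100 s and
normalised to unit mass. The lower-left corner is fast–fast behaviour, the
upper-right slow–slow.

Two groups of daily JIDs (e.g. pre-tapering vs tapering days) are compared
with a **cluster-based permutation test**: a two-sample t statistic per
bin, clusters of contiguous bins with $p < 0.01$, and a null distribution
of maximal cluster sizes from 1000 random relabellings of the days; a
cluster is significant when its size exceeds the null's 95th percentile,
and each cluster gets $p = (1 + \#\{\text{null max} \ge
\text{size}\})/(B+1)$. The convulsion day is contrasted descriptively
against the average JID of the three preceding days.

A seeded synthetic generator (`synth_config()`, `generate_study()`)
emulates the study design — 82 pre-taper / 12 taper / 91 post-taper days,
median ≈ 3311 interactions per day, nightly no-use gaps, a tapering shift
toward fast pairs and a convulsion-day shift toward slow pairs — so the
whole pipeline is testable without subject data. See
`vignettes/touchscreen-dynamics.Rmd` for the model, parameter meanings and
validation design.

## Worked example

```r
library(tapjid)

cfg <- synth_config(seed = 42)          # synthetic 82/12/91-day study
study <- generate_study(cfg)
summarize_study(study)
#> 185 study days, 653,386 interactions total
#>   daily interactions: median 3279 (IQR 2439-4622)

stream <- study_stream(study)           # one continuous tap stream
days <- split_days(stream, detect_rise_times(stream))
jids <- daily_jids(days)                # one 50x50 JID per day
design <- design_from_study(study)

tt <- run_transition_tests(jids, design, B = 1000, seed = 42)
tt
#> == Pre-tapering vs tapering ==
#> Cluster-based permutation test: 82 vs 12 daily JIDs, B = 1000
#>   cluster-forming p < 0.01, 4-connectivity; null max size: median 6 (95% CI 0 to 36), 95th pct 25.0
#>   4 cluster(s); largest:
#>  sign size     p_value significant
#>     1 1049 0.000999001        TRUE
#>    -1  449 0.000999001        TRUE
#>     1   14 0.143856144       FALSE
#>    -1    2 0.932067932       FALSE
#> == Tapering vs post-tapering ==
#> Cluster-based permutation test: 12 vs 91 daily JIDs, B = 1000
#>   cluster-forming p < 0.01, 4-connectivity; null max size: median 7 (95% CI 0 to 50), 95th pct 25.0
#>   5 cluster(s); largest:
#>  sign size     p_value significant
#>    -1  706 0.000999001        TRUE
#>     1  435 0.001998002        TRUE
#>    -1  287 0.003996004        TRUE
#>    -1   13 0.196803197       FALSE
#>    -1    6 0.610389610       FALSE
#> Fast-fast net mass: taper - pre +0.1409, post - taper -0.1357

run_seizure_contrast(jids, design)
#> Convulsion-day contrast: day_091 vs mean of 3 preceding day(s)
#>   net mass change: fast-fast -0.4826, slow-slow +0.4565, mixed +0.0260
```

Reading the output: both medication-transition tests find clusters far
larger than anything in their permutation nulls (p ≈ 0.001). The signed
fast–fast mass shows the direction — probability mass moves *into* the
fast–fast quadrant during tapering (+0.14) and back out when medication
restarts (−0.14) — and the convulsion day shifts mass strongly into the
slow–slow quadrant (+0.46) relative to the three days before it, i.e.
markedly slowed next-interval dynamics.

The same analysis runs from a YAML config, writing all artifacts
(segmentation report, per-day JID files, serialised test results, run
manifest) to disk:

```r
run_full_pipeline("config.yaml", out_dir = "results_run")
```

or from the shell via the thin wrapper `inst/cli/tapjid.R`
(`simulate` and `run` subcommands).

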