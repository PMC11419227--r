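---
title: "Rest-activity rhythm analysis with rarkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rest-activity rhythm analysis with rarkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarkit)
library(dplyr)
```

## The problem

Wrist actigraphy records movement intensity as integer "counts" per fixed
epoch (30 s or 60 s), continuously over days to weeks. From such a series the
rest-activity rhythm (RAR) — the roughly 24-hour alternation of rest and
activity — can be summarised by a small set of per-subject metrics that are
comparable across clinical cohorts: how high the rhythm is (amplitude,
mesor), when it peaks (acrophase), how square and reliable its waveform is
(the pseudo-F of a sigmoidally transformed cosine), how fragmented and how
reproducible day-to-day it is (intradaily variability IV, interdaily
stability IS), and how much actigraphic "sleep" it contains (runs of zero
counts). `rarkit` implements this pipeline end-to-end: epoch CSVs in,
a tidy per-subject metric table out, plus cohort-level averaged actograms,
k-means phenotyping and ANOVA group comparisons.

## Day alignment

All metrics are defined on whole calendar days. `trim_to_full_days()`
discards the partial-day tails of a recording, keeping the epochs from the
first midnight at or after the start up to the last midnight within the
recording; fewer than one complete day is an error. Timestamps are treated
as naive local clock time (stored as UTC internally): daylight-saving
transitions are not modelled, and a 23- or 25-hour civil day would be
rejected as irregular spacing. This keeps every downstream metric a pure
function of a `days × epochs-per-day` array. Missing or negative epochs are
hard errors, never imputed — continuous-wear recordings without gaps are a
precondition, and long zero runs are interpreted as rest, not as off-wrist
time (no non-wear detection is attempted).

## The parametric fits

**Cosinor.** `fit_cosinor()` solves the linearised single-component model
$y(t) = M + \beta\cos(\omega t) + \gamma\sin(\omega t)$, $\omega = 2\pi/24$,
by ordinary least squares on epoch-level counts and reports
$A = \sqrt{\beta^2 + \gamma^2}$ (amplitude), $\phi =
\mathrm{atan2}(\gamma,\beta)/\omega \bmod 24$ (acrophase, clock hours of the
fitted peak) and $M$ (mesor). The period is fixed at 24 h and the solution
is closed-form, so recovery on model-generated data is exact to numerical
precision. We fit at native epoch resolution rather than on hourly totals:
$A$, $\phi$ and $M$ are essentially insensitive to the binning, and
epoch-level residuals keep the residual sum of squares on the same footing
as the extended model's.

**Extended sigmoidal cosine.** Real profiles are square-ish, so
`fit_extended_cosine()` fits
$r(t) = \mathrm{min} + \mathrm{amp}\cdot\mathrm{logistic}\!\big(\beta
(\cos(\omega(t-\phi)) - \alpha)\big)$ — five parameters; $\alpha \in (-1,1)$
sets the fraction of the day in the active state and $\beta > 0$ the
steepness of the rest/active transitions. Robustness is the pseudo-F,
$F = \frac{(SS_0 - SS_{res})/(p-1)}{SS_{res}/(n-p)}$ with $p = 5$
(numerator df configurable via `df_numerator`), and since longer recordings
alone inflate $F$ roughly linearly, the reported summary is `F_per_day =
pseudo_F / days`. Absolute pseudo-F values depend on the sampling
convention (epoch-level here); only contrasts within one convention are
meaningful.

Numerical choices: the optimiser is Levenberg-Marquardt (`minpack.lm`)
with an analytic Jacobian and a fixed, deterministic multi-start grid —
phase offsets $\{0,\pm2,\pm4\}$ h around the cosinor acrophase crossed
with $\beta_0 \in \{1, 5, 20\}$, the threshold started at
$\alpha_0 = \cos(\pi f)$ where $f$ is the fraction of epochs above mean
activity, and the amplitude start floored at the data's standard deviation
so near-flat recordings do not start in a numerically singular corner. The
start with the lowest residual sum of squares wins; exact ties break to the
smaller $\beta$. A start that stalls at the iteration cap with a finite,
stable residual sum is kept as a candidate (on very noisy data the
objective flattens and the relative-reduction test never fires); the fit
errors only when every start fails outright, and the error carries the
per-start diagnostic table. No RNG is involved, so the fit is reproducible
without a seed. Parameter bounds: $\mathrm{amp} \ge 0$,
$\alpha \in (-0.999, 0.999)$, $\beta \in (10^{-3}, 500)$.

## Nonparametric metrics

IV and IS are computed on hourly totals of the retained days
(`hourly_totals()` sums counts within clock hours using integer epoch
arithmetic, so bin edges are exact):

$$IV = \frac{N\sum_{i=2}^{N}(x_i - x_{i-1})^2}{(N-1)\sum_i(x_i-\bar x)^2},
\qquad
IS = \frac{N\sum_{h=1}^{24}(\bar x_h - \bar x)^2}{24\sum_i(x_i-\bar x)^2}.$$

First differences run across midnights but do not wrap from the end of the
recording to its start. Useful calibration points, all verified in the test
suite: IV is exactly 4 for an alternating series, $\approx 2$ for white
noise, $2(1-\cos\omega)(1 + \cos\omega/(N-1))$ for an hourly-sampled pure
cosine; IS is exactly 1 for any 24 h-periodic series and $\approx 1/m$ for
white noise over $m$ days. A single-day recording returns IS = 1 with a
warning rather than an error, since trimming guarantees at least one day
but IS carries no information there. Both metrics are affine-invariant.

## Sleep bouts

A "sleep" bout is a maximal run of epochs with exactly zero counts lasting
at least 4 minutes (`detect_sleep_bouts()`; the tolerance and threshold are
arguments, defaulting to the strict rule). The scan is over the
concatenated days, so bouts may cross midnight; such bouts are attributed
wholly to their onset day — splitting them would distort the duration
survival curve. `summarize_sleep()` reports mean total bout minutes per
day, bouts per day, the survival function $S(d) = P(\text{duration} \ge d)$
on the sorted unique durations, and a 24-bin onset histogram;
`bout_duration_quantile(bouts, 0.10)` answers questions of the form "90% of
bouts are this long or shorter". These are estimates of sleep from
movement absence alone; no diary or device-wear information is used.

## Cohort analysis

`average_actogram()` computes the cohort profile as an average of averages:
days within subject first, then subjects with equal weight.
`smooth_profile()` smooths the 1440-point minute profile in two stages — a
centred circular moving average over the 100 nearest neighbours (window
101), then a local second-order polynomial of the same window
(Savitzky-Golay, which is exactly a local quadratic regression on an
equispaced grid), again with circular padding because minute 1439
neighbours minute 0.

`zscore_features()` standardises total daily "sleep", amplitude, acrophase
and `F_per_day` to mean 0, sd 1 (sample sd, $n-1$) over the clustering
cohort only. Acrophase is z-scored **linearly**, matching the clustering
procedure this package implements; the caveat is that 23.5 h and 0.5 h are
treated as 23 h apart, which is acceptable when the cohort's acrophases do
not straddle midnight (the presets peak mid-afternoon).

`kmeans_phenotype()` runs Lloyd k-means (squared Euclidean distance) with
2000 random initialisations of `k` distinct subjects each, keeping the
replicate with the lowest total within-cluster sum of squared distances. A
replicate producing an empty cluster is retried with freshly sampled
centers (bounded retries) — `stats::kmeans` exposes no per-iteration hook
to re-seed a single centroid, and with distinct data rows as initial
centers empty clusters are rare enough that the retry policy does not
affect the returned optimum. Labels are ordered A, B, C, … by ascending
centroid amplitude z-score, so "A" is always the weakest-rhythm phenotype;
raw k-means labels are arbitrary. `compare_groups()` is an ordinary
one-way fixed-effects ANOVA plus Tukey HSD at the pooled variance (no
Welch correction).

Where a design was genuinely open we chose: acrophase for clustering comes
from the cosinor (the only acrophase the metric set defines); z-scores are
computed over the cohort being clustered, not pooled with controls; bouts
are counted on their onset day.

## The synthetic cohort generator

Clinical actigraphy is rarely redistributable, so the package ships a
generator whose output has the statistical structure the pipeline assumes.
Per day $d$, the mean curve is the extended sigmoidal cosine with jittered
phase $\phi_d \sim \phi + N(0, \sigma_\phi)$ and amplitude
$\mathrm{amp}_d = \mathrm{amp}(1 + N(0, cv))$; counts are negative binomial
with $\mathrm{Var} = \mu + \theta\mu^2$ (Poisson at $\theta = 0$);
low-phase epochs (cosine below $\alpha$) are zeroed with probability
`zero_inflation_night`; naps are forced zero-runs at a Poisson daily rate,
placed uniformly in the high phase. The negative-binomial-plus-zero-
inflation choice is deliberate: the 4-minute bout rule needs exact zeros to
arise naturally, which a Gaussian noise model would essentially never
produce. Generation is exactly reproducible from `(spec, seed)` and leaves
the caller's RNG stream untouched; cohort subject seeds derive from one
master seed.

Three presets span weak (A: amplitude 150, wide rest phase $\alpha=0.3$,
shallow $\beta=3$, 5 naps/day, 2.5 h phase jitter, 10 days), intermediate
(B: amplitude 400, $\beta=6$, 1.5 naps/day, 1.2 h jitter, 11 days) and
hyper-robust (C: amplitude 800, $\beta=10$, $\alpha=-0.15$, 0.4 naps/day,
0.4 h jitter, 11 days) phenotypes, with counts on a counts-per-minute
scale typical of wrist devices. They were fixed once so that every group
contrast runs in the clinically expected direction — the weak phenotype
lower in amplitude, mesor, F/day and IS, higher in IV and total daily
"sleep" — and are not tuned to reproduce any particular cohort's absolute
values, which depend on device, population and recording length.

What the generator does **not** emulate: device-specific count algorithms,
off-wrist artifacts, missing data, daylight-saving shifts, weekday/weekend
structure, or seasonal drift. Tests passing on synthetic cohorts therefore
demonstrate internal correctness of the metrics and the recoverability of
planted structure, not robustness to those real-world artifacts.

## Verification strategy and problem sizes

The test suite checks every metric against an independent oracle: IV/IS
against unvectorised double-loop implementations and closed forms; bout
detection against a manual run-length scan; survival quantiles against a
sort-based construction; the actogram average against an explicit loop;
k-means against exhaustive enumeration of all 3-partitions at $n = 8$ and
against planted well-separated blobs; ANOVA against a hand-computed
textbook table and a 1000-replicate null simulation (type-I error within
[0.035, 0.065] at $\alpha = 0.05$). Monte-Carlo ensembles use 100–1000
replicates — 1000 where a replicate is cheap (closed-form metrics, ANOVA),
100–200 where each replicate is a nonlinear fit — and 2- to 21-day
synthetic recordings chosen to match what each property needs; the
end-to-end clustering check uses the full preset cohort at 15 subjects per
phenotype and recovers it with ARI = 1.

## Known limitations

- Linear (non-circular) acrophase z-scoring, as discussed above.
- Absolute pseudo-F values are convention-dependent; compare only F/day
  within one pipeline.
- No non-wear handling: a removed watch reads as a long sleep bout.
- IS/IV are computed at the 60-minute bin width only.
- No confidence intervals on extended-cosine parameters; the pseudo-F is a
  descriptive robustness index, not a calibrated test statistic, and the
  multi-start optimisation inflates its null distribution slightly above
  the nominal $F(4, n-5)$.
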