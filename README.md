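# rarkit — rest-activity rhythm analysis for wrist actigraphy

`rarkit` turns epoch-level wrist actigraphy counts (30 s or 60 s
Actiwatch-class exports) into per-subject rest-activity rhythm (RAR)
metrics and cohort-level summaries. It is aimed at researchers comparing
circadian rest-activity structure across clinical groups — for example
case/control cohorts in epilepsy, mood disorders or neurodegeneration —
who need the standard RAR metric panel as a tested, reproducible pipeline
rather than a pile of scripts.

## What it computes

After trimming each recording to whole midnight-to-midnight days, the
pipeline produces, per subject:

- **Cosinor** (closed-form least squares of
  *y(t) = M + A·cos(2π(t − φ)/24)*): mesor *M*, amplitude *A*, acrophase
  *φ* in clock hours.
- **Extended sigmoidally transformed cosine**
  *r(t) = min + amp·logistic(β(cos(2π(t − φ)/24) − α))*, fitted by
  multi-start Levenberg–Marquardt, with the **pseudo-F** robustness
  statistic *F = [(SS₀ − SSᵣ)/(p−1)] / [SSᵣ/(n−p)]* (p = 5) and its
  duration-normalised form **F/day** (longer recordings alone inflate F).
- **IV / IS** on hourly totals: intradaily variability
  *IV = N·Σ(xᵢ − xᵢ₋₁)² / [(N−1)·Σ(xᵢ − x̄)²]* (fragmentation; ≈2 for white
  noise) and interdaily stability
  *IS = N·Σₕ(x̄ₕ − x̄)² / [24·Σ(xᵢ − x̄)²]* (day-to-day reproducibility,
  in [0, 1]).
- **"Sleep" bouts**: maximal runs of zero counts lasting ≥ 4 min, with
  total daily "sleep" minutes, bouts/day, a bout-duration survival curve
  *S(d) = P(duration ≥ d)* and an onset histogram.

At cohort level: equal-subject-weight average actograms with a two-stage
smoother (101-point circular moving average, then local quadratic),
k-means RAR phenotyping (2000 replicates on z-scored sleep/amplitude/
acrophase/F-day features, best total within-cluster distance, clusters
labelled A…C by ascending amplitude), and one-way ANOVA + Tukey HSD group
comparisons. A synthetic-cohort generator with three preset phenotypes
(A weak/fragmented, B intermediate, C hyper-robust) supports testing and
power exploration without clinical data.

## Worked example

```r
library(rarkit)

# one synthetic subject, intermediate phenotype, fixed seed
subject <- generate_subject(rar_preset("B"), seed = 42)
days    <- trim_to_full_days(subject$series)
rar_metrics(days)
#> # A tibble: 1 × 13
#>   subject_id n_days mesor amplitude acrophase_h pseudo_F F_per_day  alpha  beta
#> 1 B_000042       11  169.      217.        14.7    1652.      150. 0.0904  5.38
#>      IV    IS total_daily_sleep_min bouts_per_day
#> 1 0.212 0.785                  647.          49.4
```

The subject's rhythm peaks at 14.7 h (mid-afternoon), rises ~217 counts/min
above a mesor of 169, repeats reliably day to day (IS 0.79, IV 0.21) and
contains ~647 min/day of zero-activity "sleep" across ~49 bouts.

```r
cohort  <- generate_cohort(list(rar_preset("A"), rar_preset("B"), rar_preset("C")),
                           n = 5, seed = 7)
metrics <- cohort_metrics(cohort)
cl      <- kmeans_phenotype(zscore_features(metrics), k = 3,
                            replicates = 2000, seed = 7)
cl
#> k-means RAR phenotypes: k = 3, 2000 replicates (seed 7)
#>   total sum of distances 5.2530
#>   sizes: A=5, B=5, C=5
tidy(cl)
#> # A tibble: 3 × 5
#>   cluster z_total_daily_sleep_min z_amplitude z_acrophase_h z_F_per_day
#> 1 A                         1.33       -1.09         -1.07       -1.04
#> 2 B                        -0.387      -0.156        0.352       -0.240
#> 3 C                        -0.939       1.25         0.720        1.28

compare_groups(augment(cl, metrics), "amplitude", group = "cluster")
#> One-way ANOVA on amplitude: F(2, 12) = 1.36e+03, p = 7.16e-15
#> Tukey HSD:
#>   contrast diff lwr upr    p_adj
#> 1      B-A  180 157 203 2.82e-10
#> 2      C-A  451 427 474 3.73e-14
#> 3      C-B  270 247 294 1.45e-12
```

Cluster A carries the most "sleep" and the weakest amplitude/robustness
(all z < −1), C the opposite — the generative phenotypes are recovered
exactly, and amplitude separates all three pairs.

Plot helpers: `autoplot()` on fits, cluster results and actograms;
`plot_bout_survival()` and `plot_onset_histogram()` for sleep summaries.

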