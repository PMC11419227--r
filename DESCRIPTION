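Package: rarkit
Title: Rest-Activity Rhythm Analysis for Wrist Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing rest-activity rhythms (RARs) from
    epoch-level wrist actigraphy counts. Reads Actiwatch-style epoch CSV
    exports, trims recordings to whole midnight-to-midnight days, and
    computes per-subject circadian metrics: single-component 24 h cosinor
    regression (mesor, amplitude, acrophase), the extended sigmoidally
    transformed cosine model with its duration-normalised pseudo-F
    robustness statistic, nonparametric intradaily variability (IV) and
    interdaily stability (IS) on hourly totals, and actigraphic "sleep"
    bouts detected as runs of zero activity of at least four minutes, with
    bout-duration survival curves and onset histograms. Cohort-level tools
    build smoothed average actograms, cluster subjects into RAR phenotypes
    by replicated k-means on z-scored features, and compare groups by
    one-way ANOVA with Tukey HSD post-hoc tests. A synthetic-cohort
    generator with three preset phenotypes supports end-to-end testing
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
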