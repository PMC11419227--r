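#' Specify a synthetic rest-activity phenotype
#'
#' Defines the generative model for one synthetic actigraphy subject. The
#' daily mean curve is the extended sigmoidal cosine,
#' \deqn{\mu_d(t) = \max\{0,\; \mathrm{minimum} + \mathrm{amp}_d \cdot
#'   \mathrm{logistic}(\beta(\cos(2\pi(t-\phi_d)/24) - \alpha))\},}
#' with day-specific phase \eqn{\phi_d = \mathrm{acrophase} +
#' N(0, \mathrm{phase\_jitter\_sd\_h})} and amplitude
#' \eqn{\mathrm{amp}_d = \mathrm{amplitude}(1 + N(0,
#' \mathrm{amplitude\_jitter\_cv}))} (floored at 0). Counts are drawn as
#' overdispersed nonnegative integers, negative binomial with
#' `Var = mu + dispersion * mu^2` (`dispersion = 0` degrades to Poisson).
#' Epochs in the low phase (cosine below the `sigmoid_alpha` threshold)
#' are additionally zeroed with probability `zero_inflation_night`, so
#' genuine zero-count rest runs occur — a purely Gaussian noise model
#' would almost never produce the exact zeros the 4-minute bout rule
#' needs. Daytime naps are inserted as forced zero-runs (rest) at a
#' Poisson rate per day.
#'
#' @param name Phenotype label.
#' @param mesor Baseline floor of the mean curve, counts/epoch
#'   (the `minimum` of the sigmoidal model).
#' @param amplitude Rise of the mean curve above the floor, counts/epoch.
#' @param acrophase_h Mean peak time, clock hours in \[0, 24).
#' @param sigmoid_beta Steepness of the sigmoidal transform (> 0).
#' @param sigmoid_alpha Threshold in (-1, 1); larger = narrower active phase.
#' @param noise_dispersion Negative-binomial overdispersion (>= 0).
#' @param zero_inflation_night Probability a low-phase epoch is exactly 0.
#' @param nap_rate_per_day Mean number of daytime naps per day (>= 0).
#' @param nap_length_min Length-2 vector `c(mean, sd)` of nap length, minutes.
#' @param phase_jitter_sd_h Day-to-day acrophase wobble, hours (drives IS
#'   down).
#' @param amplitude_jitter_cv Day-to-day amplitude coefficient of variation.
#' @param days Number of full recording days.
#' @param epoch_seconds Epoch length, 30 or 60 s.
#' @return A list of class `phenotype_spec`.
#' @seealso [rar_preset()], [generate_subject()]
#' @export
phenotype_spec <- function(name = "custom",
                           mesor = 5, amplitude = 400, acrophase_h = 14,
                           sigmoid_beta = 6, sigmoid_alpha = 0,
                           noise_dispersion = 0.8,
                           zero_inflation_night = 0.9,
                           nap_rate_per_day = 1.5,
                           nap_length_min = c(15, 5),
                           phase_jitter_sd_h = 1.2,
                           amplitude_jitter_cv = 0.15,
                           days = 11, epoch_seconds = 60) {
  spec <- list(
    name = name, mesor = mesor, amplitude = amplitude,
    acrophase_h = acrophase_h, sigmoid_beta = sigmoid_beta,
    sigmoid_alpha = sigmoid_alpha, noise_dispersion = noise_dispersion,
    zero_inflation_night = zero_inflation_night,
    nap_rate_per_day = nap_rate_per_day,
    nap_length_min = nap_length_min,
    phase_jitter_sd_h = phase_jitter_sd_h,
    amplitude_jitter_cv = amplitude_jitter_cv,
    days = as.integer(days), epoch_seconds = as.integer(epoch_seconds)
  )
  with(spec, {
    stopifnot(
      amplitude >= 0, mesor >= 0,
      acrophase_h >= 0, acrophase_h < 24,
      sigmoid_beta > 0, sigmoid_alpha > -1, sigmoid_alpha < 1,
      noise_dispersion >= 0,
      zero_inflation_night >= 0, zero_inflation_night <= 1,
      nap_rate_per_day >= 0, length(nap_length_min) == 2,
      nap_length_min[1] > 0, nap_length_min[2] >= 0,
      phase_jitter_sd_h >= 0, amplitude_jitter_cv >= 0,
      days >= 1, epoch_seconds %in% c(30L, 60L)
    )
  })
  structure(spec, class = "phenotype_spec")
}

#' Preset synthetic phenotypes A, B and C
#'
#' Three built-in phenotypes spanning the spectrum seen in clinical
#' actigraphy cohorts:
#' \describe{
#'   \item{A}{hypoactive, hypersomnic and fragmented — low amplitude, wide
#'     rest phase, frequent naps, strong day-to-day phase wobble.}
#'   \item{B}{intermediate — moderate amplitude and consolidation.}
#'   \item{C}{hyper-robust — high amplitude, steep square-ish waveform,
#'     stable phase, few naps.}
#' }
#' The presets differ in the directions that separate weak from robust
#' rhythms (amplitude, robustness, stability, fragmentation, total daily
#' "sleep"); absolute levels are package conventions, not reproductions of
#' any particular cohort.
#'
#' @param name `"A"`, `"B"` or `"C"`.
#' @param ... Overrides passed on to [phenotype_spec()].
#' @return A `phenotype_spec`.
#' @export
#' @examples
#' rar_preset("A")$amplitude < rar_preset("C")$amplitude
rar_preset <- function(name = c("A", "B", "C"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    A = list(
      name = "A", mesor = 2, amplitude = 150, acrophase_h = 13,
      sigmoid_beta = 3, sigmoid_alpha = 0.3, noise_dispersion = 1.5,
      zero_inflation_night = 0.88, nap_rate_per_day = 5,
      nap_length_min = c(25, 10), phase_jitter_sd_h = 2.5,
      amplitude_jitter_cv = 0.35, days = 10
    ),
    B = list(
      name = "B", mesor = 5, amplitude = 400, acrophase_h = 14,
      sigmoid_beta = 6, sigmoid_alpha = 0, noise_dispersion = 0.8,
      zero_inflation_night = 0.90, nap_rate_per_day = 1.5,
      nap_length_min = c(15, 5), phase_jitter_sd_h = 1.2,
      amplitude_jitter_cv = 0.15, days = 11
    ),
    C = list(
      name = "C", mesor = 8, amplitude = 800, acrophase_h = 14.5,
      sigmoid_beta = 10, sigmoid_alpha = -0.15, noise_dispersion = 0.4,
      zero_inflation_night = 0.92, nap_rate_per_day = 0.4,
      nap_length_min = c(10, 4), phase_jitter_sd_h = 0.4,
      amplitude_jitter_cv = 0.08, days = 11
    )
  )
  do.call(phenotype_spec, utils::modifyList(base, list(...)))
}

#' Generate one synthetic actigraphy subject
#'
#' Draws a full multi-day epoch series from a [phenotype_spec()]. Fully
#' reproducible: the same `(spec, seed)` pair yields an identical series
#' on any platform (Mersenne-Twister stream, integer counts). The
#' caller's RNG state is left untouched.
#'
#' @param spec A [phenotype_spec()].
#' @param seed Integer seed.
#' @param subject_id Subject identifier (default derived from
#'   `spec$name` and `seed`).
#' @param start Timestamp of the first epoch (a midnight; default
#'   2024-01-01 00:00).
#' @return A list of class `synthetic_subject`: `series` (an
#'   [epoch_series()]) and `truth` (the spec plus a tibble `realized` of
#'   per-day phases and amplitudes).
#' @export
#' @examples
#' subj <- generate_subject(rar_preset("B"), seed = 42)
#' subj$series
generate_subject <- function(spec, seed, subject_id = NULL,
                             start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(spec, "phenotype_spec"))
  subject_id <- subject_id %||% sprintf("%s_%06d", spec$name, seed %% 1000000L)
  ep <- spec$epoch_seconds
  per_day <- 86400L %/% ep
  t_day <- seq(0, 24 - ep / 3600, by = ep / 3600)

  with_local_seed(seed, {
    phases <- spec$acrophase_h + rnorm(spec$days, 0, spec$phase_jitter_sd_h)
    amps <- pmax(0, spec$amplitude * (1 + rnorm(spec$days, 0, spec$amplitude_jitter_cv)))
    counts <- integer(0)
    realized <- tibble::tibble(day = seq_len(spec$days),
                               phase_h = phases, amp = amps)
    for (d in seq_len(spec$days)) {
      cosine <- cos(2 * pi * (t_day - phases[d]) / 24)
      mu <- pmax(0, spec$mesor +
                   amps[d] * stats::plogis(spec$sigmoid_beta * (cosine - spec$sigmoid_alpha)))
      x <- if (spec$noise_dispersion > 0) {
        rnbinom(per_day, mu = mu, size = 1 / spec$noise_dispersion)
      } else {
        rpois(per_day, mu)
      }
      low <- cosine < spec$sigmoid_alpha
      x[low & stats::runif(per_day) < spec$zero_inflation_night] <- 0L
      # daytime naps: forced zero-runs in the high phase
      n_naps <- rpois(1, spec$nap_rate_per_day)
      high_idx <- which(!low)
      if (n_naps > 0 && length(high_idx) > 0) {
        onsets <- sample(high_idx, n_naps, replace = TRUE)
        lens <- pmax(1, round(rnorm(n_naps, spec$nap_length_min[1],
                                    spec$nap_length_min[2])))
        for (j in seq_len(n_naps)) {
          span <- onsets[j]:min(per_day, onsets[j] + lens[j] * 60 %/% ep - 1L)
          x[span] <- 0L
        }
      }
      counts <- c(counts, as.integer(x))
    }
    series <- epoch_series(start + ep * (seq_along(counts) - 1), counts,
                           subject_id = subject_id)
    structure(
      list(series = series, truth = c(unclass(spec), list(realized = realized))),
      class = "synthetic_subject"
    )
  })
}

#' Generate a labelled synthetic cohort
#'
#' Generates `n` subjects per phenotype and returns a manifest with true
#' phenotype labels. Per-subject seeds are derived deterministically from
#' the master seed, so the same call reproduces the identical cohort
#' byte-for-byte. When `dir` is given, per-subject epoch CSVs and a
#' `manifest.csv` are written in the dialect [read_epoch_csv()] reads;
#' otherwise the series stay in memory as a list-column.
#'
#' @param specs A list of [phenotype_spec()] objects (e.g.
#'   `list(rar_preset("A"), rar_preset("B"))`).
#' @param n Subjects per spec; recycled to `length(specs)`.
#' @param seed Master integer seed.
#' @param dir Optional output directory for CSV files.
#' @return A tibble manifest with columns `subject_id`, `group` (the spec
#'   name), `seed`, and either `path` (when written to `dir`) or a
#'   `series` list-column.
#' @export
#' @examples
#' cohort <- generate_cohort(list(rar_preset("A"), rar_preset("C")),
#'                           n = 2, seed = 7)
#' cohort$subject_id
generate_cohort <- function(specs, n, seed, dir = NULL) {
  stopifnot(length(specs) >= 1, all(n >= 1))
  n <- rep_len(n, length(specs))
  total <- sum(n)
  subject_seeds <- with_local_seed(seed, sample.int(2147483646L, total))

  plan <- purrr::map2(specs, n, \(s, k) replicate(k, s, simplify = FALSE)) |>
    purrr::flatten()
  groups <- unlist(purrr::map2(specs, n, \(s, k) rep(s$name, k)))
  ids <- sprintf("%s%02d", groups, unlist(lapply(n, seq_len)))

  subjects <- purrr::pmap(
    list(plan, subject_seeds, ids),
    \(sp, sd, id) generate_subject(sp, seed = sd, subject_id = id)
  )
  manifest <- tibble::tibble(subject_id = ids, group = groups,
                             seed = subject_seeds)
  if (is.null(dir)) {
    manifest$series <- purrr::map(subjects, "series")
    return(manifest)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest$path <- file.path(dir, paste0(ids, ".csv"))
  purrr::walk2(subjects, manifest$path, \(s, p) write_epoch_csv(s$series, p))
  readr::write_csv(manifest[c("subject_id", "path", "group")],
                   file.path(dir, "manifest.csv"), progress = FALSE)
  manifest
}
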