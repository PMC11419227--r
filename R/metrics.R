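#' Compute all rest-activity metrics for one recording
#'
#' Runs the full per-subject pipeline on a trimmed recording: 24 h cosinor
#' (mesor, amplitude, acrophase), extended sigmoidal-cosine fit (pseudo-F
#' and its duration-normalised form), nonparametric IV and IS on hourly
#' totals, and zero-activity sleep-bout estimates.
#'
#' @param dm An `rar_days` tibble from [trim_to_full_days()].
#' @param ... Passed on to [fit_extended_cosine()].
#' @return A one-row tibble: `subject_id`, `n_days`, `mesor`, `amplitude`,
#'   `acrophase_h`, `pseudo_F`, `F_per_day`, `alpha`, `beta`, `IV`, `IS`,
#'   `total_daily_sleep_min`, `bouts_per_day`.
#' @seealso [cohort_metrics()]
#' @export
#' @examples
#' days <- trim_to_full_days(generate_subject(rar_preset("B"), seed = 3)$series)
#' rar_metrics(days)
rar_metrics <- function(dm, ...) {
  assert_rar_days(dm)
  cosinor <- fit_cosinor(dm)
  extended <- fit_extended_cosine(dm, ...)
  np <- nonparametric_metrics(dm)
  sleep <- summarize_sleep(detect_sleep_bouts(dm), days = n_days(dm))

  tibble::tibble(
    subject_id = attr(dm, "subject_id"),
    n_days = n_days(dm),
    mesor = cosinor$mesor,
    amplitude = cosinor$amplitude,
    acrophase_h = cosinor$acrophase,
    pseudo_F = extended$pseudo_F,
    F_per_day = extended$F_per_day,
    alpha = extended$alpha,
    beta = extended$beta,
    IV = np$IV,
    IS = np$IS,
    total_daily_sleep_min = sleep$total_daily_sleep_min,
    bouts_per_day = sleep$bouts_per_day
  )
}

#' Per-subject metrics for a whole cohort
#'
#' Maps [rar_metrics()] over a cohort manifest. The manifest may come from
#' [read_manifest()] (files on disk, column `path`) or from
#' [generate_cohort()] with in-memory series (list-column `series`).
#'
#' @param manifest Tibble with `subject_id`, `group`, and `path` or
#'   `series`.
#' @param ... Passed on to [rar_metrics()].
#' @return A tibble with one metrics row per subject plus `group`.
#' @export
cohort_metrics <- function(manifest, ...) {
  stopifnot(is.data.frame(manifest),
            all(c("subject_id", "group") %in% names(manifest)))
  get_series <- if ("series" %in% names(manifest)) {
    function(i) manifest$series[[i]]
  } else if ("path" %in% names(manifest)) {
    function(i) read_epoch_csv(manifest$path[i],
                               subject_id = manifest$subject_id[i])
  } else {
    abort("manifest needs a `path` or `series` column.")
  }
  purrr::map(seq_len(nrow(manifest)), function(i) {
    dm <- trim_to_full_days(get_series(i))
    attr(dm, "subject_id") <- manifest$subject_id[i]
    dplyr::mutate(rar_metrics(dm, ...),
                  group = manifest$group[i], .after = "subject_id")
  }) |>
    purrr::list_rbind()
}
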