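#' Detect actigraphic "sleep" bouts
#'
#' A "sleep" bout (the quotes are deliberate: this is an actigraphic
#' estimate, not polysomnography) is a maximal run of epochs with zero
#' activity lasting at least `min_duration_min` minutes (default 4). The
#' scan runs over the concatenated epochs of all retained days, so bouts
#' may cross midnight; a midnight-crossing bout is attributed wholly to
#' the day on which it starts, keeping bout durations faithful for the
#' survival curve.
#'
#' @param dm An `rar_days` tibble from [trim_to_full_days()].
#' @param min_duration_min Minimum bout duration in minutes (default 4).
#' @param zero_tolerance Counts at or below this value are treated as
#'   "zero activity". Default 0: only exact zeros qualify.
#' @return A tibble with one row per bout, chronological, columns
#'   `onset_day` (1-based day index of the first epoch), `onset_hour`
#'   (clock hour of onset, \[0, 24)), `duration_min`, and `n_epochs`.
#' @seealso [summarize_sleep()]
#' @export
detect_sleep_bouts <- function(dm, min_duration_min = 4, zero_tolerance = 0) {
  assert_rar_days(dm)
  ep_min <- attr(dm, "epoch_seconds") / 60
  r <- rle(dm$counts <= zero_tolerance)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values & (r$lengths * ep_min >= min_duration_min)

  tibble::tibble(
    onset_day = dm$day[run_start[keep]],
    onset_hour = dm$time_h[run_start[keep]],
    duration_min = r$lengths[keep] * ep_min,
    n_epochs = r$lengths[keep]
  )
}

#' Summarise detected sleep bouts
#'
#' Aggregates a bout list into the per-subject sleep estimates: mean total
#' bout minutes per day, mean bout count per day, the bout-duration
#' survival function \eqn{S(d) = P(\mathrm{duration} \ge d)} evaluated at
#' the sorted unique durations, and a 24-bin histogram of bout onsets by
#' clock hour. An empty bout list is valid (a pathologically active
#' subject) and yields zeros with an empty survival table.
#'
#' @param bouts Tibble from [detect_sleep_bouts()].
#' @param days Number of retained recording days (`>= 1`).
#' @return An object of class `sleep_summary`: list with
#'   `total_daily_sleep_min`, `bouts_per_day`, `n_bouts`, `days`,
#'   `survival` (tibble `duration_min`, `surviving`), and `onset_hist`
#'   (tibble `hour` 0-23, `n`).
#' @export
summarize_sleep <- function(bouts, days) {
  stopifnot(days >= 1)
  d <- sort(unique(bouts$duration_min))
  survival <- tibble::tibble(
    duration_min = d,
    surviving = vapply(d, function(x) mean(bouts$duration_min >= x), numeric(1))
  )
  onset_hist <- tibble::tibble(hour = 0:23) |>
    dplyr::left_join(
      dplyr::count(bouts, hour = floor(.data$onset_hour)),
      by = "hour"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))

  structure(
    list(
      total_daily_sleep_min = sum(bouts$duration_min) / days,
      bouts_per_day = nrow(bouts) / days,
      n_bouts = nrow(bouts),
      days = days,
      survival = survival,
      onset_hist = onset_hist
    ),
    class = "sleep_summary"
  )
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat(sprintf(
    "Sleep summary: %d bouts over %d day(s)\n  total daily \"sleep\" %.1f min/day, %.2f bouts/day\n",
    x$n_bouts, x$days, x$total_daily_sleep_min, x$bouts_per_day
  ))
  invisible(x)
}

#' Bout-duration survival quantile
#'
#' The smallest duration `d` at which the survival fraction drops to
#' `level` or below — e.g. `level = 0.10` answers "90% of bouts are this
#' long or shorter".
#'
#' @param bouts Tibble from [detect_sleep_bouts()] (or a `sleep_summary`).
#' @param level Target surviving fraction in (0, 1\].
#' @return Duration in minutes (`NA` if there are no bouts).
#' @export
bout_duration_quantile <- function(bouts, level = 0.10) {
  if (inherits(bouts, "sleep_summary")) {
    surv <- bouts$survival
  } else {
    surv <- summarize_sleep(bouts, days = 1)$survival
  }
  if (nrow(surv) == 0L) return(NA_real_)
  ok <- surv$duration_min[surv$surviving <= level]
  if (length(ok) == 0L) max(surv$duration_min) else min(ok)
}

#' Plot the bout-duration survival curve
#'
#' Fraction of bouts surviving to each duration, on a log-scaled y axis as
#' is conventional for bout-duration distributions.
#'
#' @param summary A `sleep_summary` (or a list of them, named by group).
#' @return A ggplot object.
#' @export
plot_bout_survival <- function(summary) {
  if (inherits(summary, "sleep_summary")) summary <- list(all = summary)
  df <- purrr::imap(summary, \(s, nm) dplyr::mutate(s$survival, group = nm)) |>
    purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(.data$duration_min, .data$surviving,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "bout duration (min)", y = "fraction surviving",
                  colour = NULL)
}

#' Plot the bout-onset histogram by clock hour
#'
#' @inheritParams plot_bout_survival
#' @return A ggplot object.
#' @export
plot_onset_histogram <- function(summary) {
  if (inherits(summary, "sleep_summary")) summary <- list(all = summary)
  df <- purrr::imap(summary, \(s, nm) dplyr::mutate(s$onset_hist, group = nm)) |>
    purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(.data$hour, .data$n, fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "bout onset (clock hour)", y = "bouts", fill = NULL)
}
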