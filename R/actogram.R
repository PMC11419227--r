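#' Cohort-average actogram profile
#'
#' Builds the "average of averages" 24 h activity profile of a cohort:
#' each subject's retained days are first averaged into that subject's own
#' minute-resolution profile (30 s epochs are averaged in within-minute
#' pairs), then the subject profiles are averaged with equal weight per
#' subject — a subject with 20 recording days counts no more than one
#' with 6.
#'
#' @param cohort A list of `rar_days` objects (or a single one). All must
#'   share the same epoch length.
#' @return A tibble of class `rar_actogram` with 1440 rows: `minute`
#'   (0-1439) and `mean_counts` (counts per minute-epoch, cohort mean).
#'   Attribute `n_subjects`.
#' @seealso [smooth_profile()], [smooth_actogram()]
#' @export
average_actogram <- function(cohort) {
  if (inherits(cohort, "rar_days")) cohort <- list(cohort)
  stopifnot(length(cohort) >= 1)
  eps <- vapply(cohort, function(dm) attr(dm, "epoch_seconds"), numeric(1))
  if (length(unique(eps)) != 1L) {
    abort("mixed epoch lengths in cohort; resample before averaging.")
  }
  profiles <- purrr::map(cohort, subject_minute_profile)
  mean_profile <- Reduce(`+`, profiles) / length(profiles)
  out <- tibble::tibble(minute = 0:1439, mean_counts = mean_profile)
  structure(out,
    class = c("rar_actogram", class(out)),
    n_subjects = length(cohort)
  )
}

# one subject's day-averaged minute profile (length 1440)
subject_minute_profile <- function(dm) {
  assert_rar_days(dm)
  ep <- attr(dm, "epoch_seconds")
  per_day <- 86400L %/% ep
  prof <- dm |>
    dplyr::mutate(
      minute = (((dplyr::row_number() - 1L) %% per_day) * ep) %/% 60L
    ) |>
    dplyr::summarise(m = mean(.data$counts), .by = "minute") |>
    dplyr::arrange(.data$minute)
  prof$m
}

#' Smooth a 1440-point minute profile
#'
#' Two-stage smoother for cohort actogram profiles: (1) a centred moving
#' average over the 100 nearest neighbours (window of 101 points), then
#' (2) a local second-order polynomial (Savitzky-Golay) filter of the same
#' window applied to the stage-1 output. Both stages use circular
#' (wrap-at-midnight) padding, because the profile is a clock: minute 1439
#' neighbours minute 0.
#'
#' @param profile Numeric vector of length 1440 (counts per minute).
#' @param window Odd window length covering the "nearest neighbours"
#'   (default 101).
#' @return Numeric vector of length 1440.
#' @export
smooth_profile <- function(profile, window = 101) {
  stopifnot(length(profile) == 1440, window %% 2 == 1, window < 1440)
  # stage 1: circular centred moving average
  stage1 <- as.numeric(stats::filter(profile, rep(1 / window, window),
                                     sides = 2, circular = TRUE))
  # stage 2: local quadratic (Savitzky-Golay) on circularly padded series
  half <- (window - 1) / 2
  padded <- c(tail(stage1, half), stage1, head(stage1, half))
  sm <- signal::sgolayfilt(padded, p = 2, n = window)
  sm[(half + 1):(half + 1440)]
}

#' Add a smoothed column to an actogram profile
#'
#' @param actogram An `rar_actogram` from [average_actogram()].
#' @inheritParams smooth_profile
#' @return The actogram tibble with an added `smoothed` column.
#' @export
smooth_actogram <- function(actogram, window = 101) {
  stopifnot(inherits(actogram, "rar_actogram"))
  actogram$smoothed <- smooth_profile(actogram$mean_counts, window = window)
  actogram
}

#' @export
autoplot.rar_actogram <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"minute",
    names_to = "series", values_to = "counts"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$minute / 60, .data$counts,
                                   linewidth = .data$series)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_linewidth_manual(
      values = c(mean_counts = 0.3, smoothed = 1),
      guide = "none"
    ) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "clock time (h)", y = "counts / min",
                  title = sprintf("Average actogram (%d subject%s)",
                                  attr(object, "n_subjects"),
                                  if (attr(object, "n_subjects") == 1) "" else "s"))
}
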