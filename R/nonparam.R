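#' Intradaily variability (IV)
#'
#' IV quantifies rhythm fragmentation as the normalised mean square of
#' successive differences of the hourly totals:
#' \deqn{IV = \frac{N \sum_{i=2}^{N} (x_i - x_{i-1})^2}
#'                 {(N-1) \sum_{i=1}^{N} (x_i - \bar{x})^2}.}
#' Differences run over the concatenated chronological series — they cross
#' midnights but do not wrap from the recording end to its start. A smooth
#' sinusoid gives IV near 0; white noise gives IV near 2; rapid
#' alternation can reach 4.
#'
#' @param hourly Hourly totals: a numeric vector in chronological order,
#'   or the tibble returned by [hourly_totals()].
#' @return The IV value (dimensionless, `>= 0`).
#' @seealso [interdaily_stability()]
#' @export
intradaily_variability <- function(hourly) {
  x <- as_hourly_vector(hourly)
  n <- length(x)
  if (n < 2L) abort("IV needs at least two hourly totals.")
  denom <- sum((x - mean(x))^2)
  if (denom == 0) abort("constant series: IV is undefined with zero variance.")
  n * sum(diff(x)^2) / ((n - 1) * denom)
}

#' Interdaily stability (IS)
#'
#' IS measures day-to-day reproducibility of the activity profile: the
#' fraction of the total variance of hourly totals that is explained by
#' the average 24 h profile,
#' \deqn{IS = \frac{N \sum_{h=1}^{24} (\bar{x}_h - \bar{x})^2}
#'                 {24 \sum_{i=1}^{N} (x_i - \bar{x})^2},}
#' where \eqn{\bar{x}_h} is the mean over days of the hour-`h` totals and
#' `N = 24 * days`. IS is 1 for a perfectly repeating day and has
#' expectation `1/days` for white noise.
#'
#' A single-day recording yields IS = 1 identically (every hour mean is
#' the observation itself); it is returned with a warning because it
#' carries no stability information.
#'
#' @inheritParams intradaily_variability
#' @param days Number of days; inferred from a [hourly_totals()] tibble,
#'   required for a bare vector whose length is `24 * days`.
#' @return The IS value in \[0, 1\].
#' @export
interdaily_stability <- function(hourly, days = NULL) {
  if (is.data.frame(hourly) && is.null(days)) {
    days <- dplyr::n_distinct(hourly$day)
  }
  x <- as_hourly_vector(hourly)
  if (is.null(days)) abort("`days` is required when `hourly` is a bare vector.")
  n <- length(x)
  if (n != 24L * days) abort("hourly series length must equal 24 * days.")
  if (days == 1L) {
    warn("single-day recording: IS is 1 by construction and uninformative.")
    return(1)
  }
  denom <- sum((x - mean(x))^2)
  if (denom == 0) abort("constant series: IS is undefined with zero variance.")
  hour_means <- colMeans(matrix(x, nrow = days, ncol = 24, byrow = TRUE))
  n * sum((hour_means - mean(x))^2) / (24 * denom)
}

as_hourly_vector <- function(hourly) {
  if (is.data.frame(hourly)) {
    if (!all(c("day", "hour", "total") %in% names(hourly))) {
      abort("expected columns day, hour, total (see hourly_totals()).")
    }
    hourly <- dplyr::arrange(hourly, .data$day, .data$hour)$total
  }
  if (!is.numeric(hourly)) abort("hourly totals must be numeric.")
  if (anyNA(hourly)) abort("hourly totals contain missing values.")
  as.numeric(hourly)
}

#' Nonparametric circadian metrics for one recording
#'
#' Convenience wrapper computing IV and IS from a trimmed recording.
#'
#' @param dm An `rar_days` tibble from [trim_to_full_days()].
#' @return A one-row tibble: `IV`, `IS`, `n_hours`.
#' @export
nonparametric_metrics <- function(dm) {
  assert_rar_days(dm)
  h <- hourly_totals(dm)
  tibble::tibble(
    IV = intradaily_variability(h),
    IS = interdaily_stability(h),
    n_hours = nrow(h)
  )
}
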