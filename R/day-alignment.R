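#' Trim a recording to whole midnight-to-midnight days
#'
#' Actigraphy recordings start and stop at arbitrary clock times. All
#' downstream rhythm metrics are defined on whole calendar days, so the
#' partial-day tails are discarded: epochs before the first midnight at or
#' after the recording start, and at or after the last midnight within the
#' recording. What remains is an integer number of full days ("day" =
#' midnight to midnight on the device's local clock).
#'
#' @param series An [epoch_series()].
#' @return A tibble of class `rar_days` with one row per retained epoch and
#'   columns:
#'   \describe{
#'     \item{day}{1-based index of the retained day.}
#'     \item{time_h}{clock time of the epoch start within its day, in hours
#'       (`0` to `24 - epoch/3600`).}
#'     \item{counts}{integer activity count.}
#'   }
#'   Attributes: `subject_id`, `epoch_seconds`, `n_days`, `start_midnight`.
#' @export
#' @examples
#' ts <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC") + 60 * (0:2879)
#' days <- trim_to_full_days(epoch_series(ts, rep(1L, 2880), "s01"))
#' attr(days, "n_days") # 2
trim_to_full_days <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  ep <- attr(series, "epoch_seconds")
  t0 <- as.numeric(series$timestamp[1])
  secs <- round(as.numeric(series$timestamp) - t0)
  # second-of-day of the first epoch (clock is UTC-naive by construction)
  sod0 <- round(as.numeric(series$timestamp[1])) %% 86400
  sod <- (sod0 + secs) %% 86400

  first_mid <- if (sod0 == 0) 1L else which(sod == 0)[1]
  if (is.na(first_mid)) abort("recording too short: no complete midnight-to-midnight day.")
  # end of the last epoch, relative to the first retained midnight
  total_sec <- secs[length(secs)] + ep - secs[first_mid]
  n_days <- floor(total_sec / 86400)
  if (is.na(n_days) || n_days < 1) {
    abort("recording too short: no complete midnight-to-midnight day.")
  }
  keep <- first_mid:(first_mid + n_days * 86400 / ep - 1L)
  counts <- series$counts[keep]
  per_day <- as.integer(86400 / ep)

  # time_h from integer epoch seconds: exact at whole-hour/minute boundaries
  out <- tibble::tibble(
    day = rep(seq_len(n_days), each = per_day),
    time_h = rep((seq_len(per_day) - 1) * ep, times = n_days) / 3600,
    counts = counts
  )
  structure(out,
    class = c("rar_days", class(out)),
    subject_id = attr(series, "subject_id"),
    epoch_seconds = ep,
    n_days = as.integer(n_days),
    start_midnight = series$timestamp[first_mid]
  )
}

#' @export
print.rar_days <- function(x, ...) {
  cat(sprintf(
    "<rar_days> subject %s: %d full day(s) at %d s epochs\n",
    attr(x, "subject_id"), attr(x, "n_days"), attr(x, "epoch_seconds")
  ))
  NextMethod()
}

n_days <- function(dm) attr(dm, "n_days")

assert_rar_days <- function(dm) {
  if (!inherits(dm, "rar_days")) {
    abort("expected an `rar_days` object from trim_to_full_days().")
  }
  invisible(dm)
}

#' Day-by-epoch matrix view of a trimmed recording
#'
#' @param dm An `rar_days` tibble from [trim_to_full_days()].
#' @return Numeric matrix, `n_days` rows by `86400 / epoch_seconds` columns;
#'   row `d` holds day `d` from 00:00 (inclusive) to 24:00 (exclusive).
#' @export
day_matrix <- function(dm) {
  assert_rar_days(dm)
  per_day <- as.integer(86400 / attr(dm, "epoch_seconds"))
  matrix(dm$counts, nrow = n_days(dm), ncol = per_day, byrow = TRUE,
         dimnames = list(paste0("day", seq_len(n_days(dm))), NULL))
}

#' Serialize the day matrix to CSV (one row per day) for inspection
#'
#' @inheritParams day_matrix
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_day_matrix_csv <- function(dm, path) {
  mat <- day_matrix(dm)
  df <- as.data.frame(mat)
  names(df) <- sprintf("e%04d", seq_len(ncol(mat)))
  readr::write_csv(cbind(day = seq_len(nrow(mat)), df), path, progress = FALSE)
  invisible(path)
}

#' Per-clock-hour activity totals
#'
#' Sums counts within each clock hour (00-01, 01-02, ...) of each retained
#' day, in chronological order. These hourly totals are the substrate for
#' the nonparametric metrics IV and IS.
#'
#' @inheritParams day_matrix
#' @return A tibble with `24 * n_days` rows and columns `day`, `hour`
#'   (0-23) and `total`.
#' @seealso [intradaily_variability()], [interdaily_stability()]
#' @export
hourly_totals <- function(dm) {
  assert_rar_days(dm)
  ep <- attr(dm, "epoch_seconds")
  per_day <- 86400L %/% ep
  dm |>
    dplyr::mutate(
      hour = (((dplyr::row_number() - 1L) %% per_day) * ep) %/% 3600L
    ) |>
    dplyr::summarise(total = sum(.data$counts), .by = c("day", "hour")) |>
    dplyr::arrange(.data$day, .data$hour)
}
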