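#' Construct an epoch-level activity series
#'
#' An epoch series is the raw unit of wrist actigraphy: one row per fixed
#' sampling epoch (30 s or 60 s) holding an integer activity count. The
#' series must be gap-free — actigraphy devices record continuously and a
#' missing epoch is treated as a hard error, never imputed.
#'
#' Timestamps are naive local clock time; they are stored as POSIXct in UTC
#' so that calendar arithmetic is pure (no daylight-saving transitions; a
#' 23 h or 25 h civil day would surface as irregular spacing and be
#' rejected).
#'
#' @param timestamp POSIXct vector (or strings parseable as
#'   `"%Y-%m-%d %H:%M:%S"`), strictly increasing, uniformly spaced.
#' @param counts Nonnegative integer activity counts, one per epoch.
#'   Whole-number doubles are cast; fractional or negative values error.
#' @param subject_id Single string identifying the subject.
#'
#' @return A tibble of class `epoch_series` with columns `timestamp` and
#'   `counts`, and attributes `subject_id` and `epoch_seconds`.
#' @seealso [read_epoch_csv()], [trim_to_full_days()]
#' @export
#' @examples
#' ts <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC") + 60 * (0:5)
#' epoch_series(ts, c(5L, 0L, 3L, 7L, 0L, 2L), "s01")
epoch_series <- function(timestamp, counts, subject_id = "subject") {
  if (is.character(timestamp)) {
    timestamp <- as.POSIXct(timestamp, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  }
  if (!inherits(timestamp, "POSIXct")) {
    abort("`timestamp` must be POSIXct or parseable 'YYYY-mm-dd HH:MM:SS' strings.")
  }
  attr(timestamp, "tzone") <- "UTC"
  if (anyNA(timestamp)) abort("invalid counts: unparseable or missing timestamps.")
  n <- length(timestamp)
  if (n < 1L) abort("an epoch series needs at least one epoch.")
  if (length(counts) != n) abort("`timestamp` and `counts` lengths differ.")
  counts <- check_counts(counts)

  if (n >= 2L) {
    deltas <- diff(as.numeric(timestamp))
    if (any(abs(deltas - deltas[1]) > 1e-6)) abort("irregular epochs: non-uniform timestamp spacing.")
    epoch_seconds <- deltas[1]
  } else {
    epoch_seconds <- 60
  }
  check_epoch_seconds(epoch_seconds)

  out <- tibble::tibble(timestamp = timestamp, counts = counts)
  structure(out,
    class = c("epoch_series", class(out)),
    subject_id = as.character(subject_id)[1],
    epoch_seconds = as.integer(epoch_seconds)
  )
}

check_counts <- function(counts) {
  if (anyNA(counts)) abort("invalid counts: missing values are not allowed.")
  if (!is.numeric(counts)) abort("invalid counts: non-numeric entries.")
  if (any(counts < 0)) abort("invalid counts: negative activity counts.")
  if (any(abs(counts - round(counts)) > 1e-9)) {
    abort("invalid counts: activity counts must be whole numbers.")
  }
  as.integer(round(counts))
}

check_epoch_seconds <- function(epoch_seconds) {
  if (!isTRUE(epoch_seconds %in% c(30, 60))) {
    abort(sprintf(
      "irregular epochs: epoch length %.6g s is not supported (must be 30 or 60).",
      epoch_seconds
    ))
  }
  invisible(as.integer(epoch_seconds))
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> subject %s: %d epochs of %d s, %s to %s\n",
    attr(x, "subject_id"), nrow(x), attr(x, "epoch_seconds"),
    format(x$timestamp[1], "%Y-%m-%d %H:%M"),
    format(x$timestamp[nrow(x)], "%Y-%m-%d %H:%M")
  ))
  NextMethod()
}

#' Read an epoch-level actigraphy CSV export
#'
#' Parses a delimited text export with one row per epoch (the dialect
#' written by Actiwatch-class software after conversion to CSV): a header
#' row, a timestamp column and an integer counts column. Epoch length is
#' inferred from consecutive timestamp differences unless a hint is given.
#'
#' @param path Path to the CSV file.
#' @param epoch_seconds_hint Optional epoch length in seconds (30 or 60).
#'   Required only when the file has a single row, where spacing cannot be
#'   inferred.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param timestamp_col,counts_col Column names in the file header.
#'   Vendor exports vary; override these rather than renaming files.
#' @return An [epoch_series()].
#' @export
read_epoch_csv <- function(path, epoch_seconds_hint = NULL,
                           subject_id = NULL,
                           timestamp_col = "timestamp",
                           counts_col = "activity") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  for (col in c(timestamp_col, counts_col)) {
    if (!col %in% names(raw)) {
      abort(sprintf("column '%s' not found in %s (header: %s).",
                    col, path, paste(names(raw), collapse = ", ")))
    }
  }
  counts <- suppressWarnings(as.numeric(raw[[counts_col]]))
  if (anyNA(counts)) abort("invalid counts: non-numeric or missing entries.")
  subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))

  series <- epoch_series(raw[[timestamp_col]], counts, subject_id = subject_id)
  if (!is.null(epoch_seconds_hint) &&
      attr(series, "epoch_seconds") != as.integer(epoch_seconds_hint)) {
    if (nrow(series) > 1L) {
      abort(sprintf(
        "irregular epochs: file spacing %d s contradicts hint %d s.",
        attr(series, "epoch_seconds"), as.integer(epoch_seconds_hint)
      ))
    }
    attr(series, "epoch_seconds") <- check_epoch_seconds(as.numeric(epoch_seconds_hint))
  }
  if (nrow(series) == 1L && is.null(epoch_seconds_hint)) {
    abort("ambiguous epoch length for a single-row file; pass `epoch_seconds_hint`.")
  }
  series
}

#' Write an epoch series back to CSV
#'
#' Inverse of [read_epoch_csv()]: writes the same two-column dialect, so a
#' read/write round trip reproduces the file (modulo line endings).
#'
#' @inheritParams read_epoch_csv
#' @param series An [epoch_series()].
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path,
                            timestamp_col = "timestamp",
                            counts_col = "activity") {
  stopifnot(inherits(series, "epoch_series"))
  out <- data.frame(
    a = format(series$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    b = series$counts
  )
  names(out) <- c(timestamp_col, counts_col)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest maps subject IDs to their epoch CSV files and group labels
#' (e.g. case and control cohorts). Columns: `subject_id`, `path`, `group`.
#'
#' @param path Manifest CSV path.
#' @param check_paths Verify every referenced file exists (default `TRUE`).
#'   Relative paths are resolved against the manifest's directory.
#' @return A tibble with columns `subject_id`, `path`, `group`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    path = readr::col_character(),
    group = readr::col_character()
  ), progress = FALSE)
  if (anyDuplicated(m$subject_id)) abort("manifest subject_ids must be unique.")
  m$path <- ifelse(
    file.exists(m$path), m$path,
    file.path(dirname(path), m$path)
  )
  if (check_paths && !all(file.exists(m$path))) {
    missing <- m$path[!file.exists(m$path)]
    abort(sprintf("manifest references missing files: %s",
                  paste(missing, collapse = ", ")))
  }
  m
}
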