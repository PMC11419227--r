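test_that("read_epoch_csv parses a simple 60 s export", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,activity",
    "2024-03-01 10:00:00,5",
    "2024-03-01 10:01:00,0",
    "2024-03-01 10:02:00,3",
    "2024-03-01 10:03:00,7"
  ), f)
  s <- read_epoch_csv(f)
  expect_s3_class(s, "epoch_series")
  expect_identical(attr(s, "epoch_seconds"), 60L)
  expect_identical(s$counts, c(5L, 0L, 3L, 7L))
})

test_that("irregular spacing, bad counts and missing values are hard errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,activity",
    "2024-03-01 10:00:00,5",
    "2024-03-01 10:01:00,0",
    "2024-03-01 10:03:00,3" # 120 s gap
  ), f)
  expect_error(read_epoch_csv(f), "irregular epochs")

  ts <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC") + 60 * (0:3)
  expect_error(epoch_series(ts, c(1, -2, 3, 4)), "invalid counts")
  expect_error(epoch_series(ts, c(1, NA, 3, 4)), "invalid counts")
  expect_error(epoch_series(ts, c(1, 2.5, 3, 4)), "invalid counts")
  # whole-number doubles are cast
  expect_identical(epoch_series(ts, c(1, 2, 3, 4))$counts, 1:4)
  # non-actigraphic spacing rejected
  ts2 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC") + 90 * (0:3)
  expect_error(epoch_series(ts2, 1:4), "irregular epochs")
})

test_that("single-row files need an explicit epoch hint", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,activity", "2024-03-01 10:00:00,5"), f)
  expect_error(read_epoch_csv(f), "hint")
  s <- read_epoch_csv(f, epoch_seconds_hint = 30)
  expect_identical(attr(s, "epoch_seconds"), 30L)
})

test_that("write/read round trip reproduces random synthetic files", {
  set.seed(11)
  for (i in 1:25) {
    ep <- sample(c(30L, 60L), 1)
    n <- sample(50:300, 1)
    start <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
      sample(0:86399, 1) %/% ep * ep
    s <- epoch_series(start + ep * (0:(n - 1)), rpois(n, 20), subject_id = "rt")
    f <- withr::local_tempfile(fileext = ".csv")
    write_epoch_csv(s, f)
    s2 <- read_epoch_csv(f, subject_id = "rt",
                         epoch_seconds_hint = ep)
    expect_identical(s2$counts, s$counts)
    expect_equal(as.numeric(s2$timestamp), as.numeric(s$timestamp))
    # and byte-level stability of a second write
    f2 <- withr::local_tempfile(fileext = ".csv")
    write_epoch_csv(s2, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("trim_to_full_days keeps exactly the midnight-to-midnight core", {
  start <- as.POSIXct("2024-03-01 15:00:00", tz = "UTC")
  end <- as.POSIXct("2024-03-05 10:00:00", tz = "UTC")
  ts <- seq(start, end - 60, by = 60)
  s <- epoch_series(ts, rep(1L, length(ts)), "trim")
  dm <- trim_to_full_days(s)
  expect_identical(attr(dm, "n_days"), 3L)
  expect_identical(nrow(dm), 3L * 1440L)
  expect_equal(
    attr(dm, "start_midnight"),
    as.POSIXct("2024-03-02 00:00:00", tz = "UTC")
  )

  # already aligned: nothing discarded, idempotent content
  ts2 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC") + 60 * (0:2879)
  s2 <- epoch_series(ts2, rpois(2880, 5), "aligned")
  dm2 <- trim_to_full_days(s2)
  expect_identical(attr(dm2, "n_days"), 2L)
  expect_identical(dm2$counts, s2$counts)

  # no full day at all
  ts3 <- seq(as.POSIXct("2024-03-01 23:00:00", tz = "UTC"),
             as.POSIXct("2024-03-02 00:29:00", tz = "UTC"), by = 60)
  expect_error(trim_to_full_days(epoch_series(ts3, rep(0L, length(ts3)))),
               "recording too short")
})

test_that("trimming conserves counts within the retained window", {
  set.seed(21)
  start <- as.POSIXct("2024-03-01 07:23:00", tz = "UTC")
  ts <- start + 60 * (0:(4 * 1440 + 200))
  counts <- rpois(length(ts), 10)
  s <- epoch_series(ts, counts, "conserve")
  dm <- trim_to_full_days(s)
  first_mid <- which(format(ts, "%H:%M:%S") == "00:00:00")[1]
  kept <- counts[first_mid:(first_mid + nrow(dm) - 1)]
  expect_identical(dm$counts, as.integer(kept))
  expect_identical(sum(day_matrix(dm)), sum(kept))
})

test_that("hourly totals match a brute-force loop and conserve the grand total", {
  set.seed(31)
  for (ep in c(30L, 60L)) {
    dm <- make_days(rpois(2 * 86400 / ep, 8), epoch_seconds = ep)
    h <- hourly_totals(dm)
    expect_identical(nrow(h), 48L)
    # loop oracle: sum epochs whose start falls within each clock hour
    per_day <- 86400 / ep
    expected <- numeric(48)
    for (i in seq_len(nrow(dm))) {
      idx <- (dm$day[i] - 1) * 24 + floor(dm$time_h[i]) + 1
      expected[idx] <- expected[idx] + dm$counts[i]
    }
    expect_equal(h$total, expected)
    expect_identical(sum(h$total), sum(dm$counts))
  }
  # all-ones 60 s day: every hour totals 60
  h1 <- hourly_totals(make_days(rep(1L, 1440)))
  expect_equal(h1$total, rep(60, 24))
  h0 <- hourly_totals(make_days(rep(0L, 1440)))
  expect_equal(h0$total, rep(0, 24))
})

test_that("cohort manifest validates uniqueness and paths", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "s1.csv")
  writeLines(c("timestamp,activity", "2024-03-01 10:00:00,5",
               "2024-03-01 10:01:00,2"), f)
  mf <- file.path(dir, "manifest.csv")
  writeLines(c("subject_id,path,group", sprintf("s1,%s,case", f)), mf)
  m <- read_manifest(mf)
  expect_identical(m$subject_id, "s1")

  writeLines(c("subject_id,path,group",
               sprintf("s1,%s,case", f), sprintf("s1,%s,ctrl", f)), mf)
  expect_error(read_manifest(mf), "unique")

  writeLines(c("subject_id,path,group", "s2,/nonexistent/file.csv,case"), mf)
  expect_error(read_manifest(mf), "missing files")
})
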