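# Independent oracles, deliberately unvectorised and written from the metric
# definitions rather than reusing any package internals.

# IV by explicit double loop
oracle_iv <- function(x) {
  n <- length(x)
  num <- 0
  for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
  den <- 0
  xb <- mean(x)
  for (i in 1:n) den <- den + (x[i] - xb)^2
  n * num / ((n - 1) * den)
}

# IS by explicit loops over hours and days
oracle_is <- function(x, days) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (h in 1:24) {
    vals <- numeric(days)
    for (d in 1:days) vals[d] <- x[(d - 1) * 24 + h]
    num <- num + (mean(vals) - xb)^2
  }
  den <- 0
  for (i in 1:n) den <- den + (x[i] - xb)^2
  n * num / (24 * den)
}

# sleep bouts by manual run-length encoding over the raw count vector
oracle_bouts <- function(counts, epoch_seconds, min_minutes = 4) {
  bouts <- list()
  i <- 1
  n <- length(counts)
  while (i <= n) {
    if (counts[i] == 0) {
      j <- i
      while (j < n && counts[j + 1] == 0) j <- j + 1
      len_min <- (j - i + 1) * epoch_seconds / 60
      if (len_min >= min_minutes) {
        bouts[[length(bouts) + 1]] <- c(start = i, n_epochs = j - i + 1)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(bouts) == 0) {
    return(data.frame(start = integer(), n_epochs = integer()))
  }
  as.data.frame(do.call(rbind, bouts))
}

# build an aligned rar_days object directly from a count vector
make_days <- function(counts, epoch_seconds = 60, subject_id = "t") {
  start <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  ts <- start + epoch_seconds * (seq_along(counts) - 1)
  trim_to_full_days(epoch_series(ts, counts, subject_id = subject_id))
}

# model-generated counts on the epoch grid: plain cosinor mean
cosinor_counts <- function(days, mesor, amplitude, acrophase,
                           epoch_seconds = 60, noise_sd = 0, round_counts = TRUE) {
  per_day <- 86400 / epoch_seconds
  t <- seq(0, days * 24 - epoch_seconds / 3600, by = epoch_seconds / 3600)
  y <- mesor + amplitude * cos(2 * pi * (t - acrophase) / 24)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  if (round_counts) pmax(0L, as.integer(round(y))) else y
}

# extended sigmoidal-cosine mean curve on the epoch grid
sigmoid_counts <- function(days, minimum, amp, phi, alpha, beta,
                           epoch_seconds = 60, noise_sd = 0) {
  t <- seq(0, days * 24 - epoch_seconds / 3600, by = epoch_seconds / 3600)
  y <- minimum + amp * plogis(beta * (cos(2 * pi * (t - phi) / 24) - alpha))
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  pmax(0L, as.integer(round(y)))
}
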