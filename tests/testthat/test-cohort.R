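make_metrics <- function(x, ids = sprintf("s%02d", seq_len(nrow(x)))) {
  m <- tibble::as_tibble(x)
  m$subject_id <- ids
  m
}

subject_profile_oracle <- function(dm) {
  mat <- day_matrix(dm)
  sapply(1:1440, function(mnt) mean(mat[, mnt]))
}

test_that("z-scoring standardises each feature over the cohort", {
  m <- make_metrics(data.frame(total_daily_sleep_min = c(100, 200),
                               amplitude = c(10, 30),
                               acrophase_h = c(12, 16),
                               F_per_day = c(5, 15)))
  z <- zscore_features(m)
  expect_equal(z$z_total_daily_sleep_min, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(191)
  m2 <- make_metrics(data.frame(
    total_daily_sleep_min = rnorm(20, 300, 50), amplitude = rgamma(20, 4),
    acrophase_h = runif(20, 10, 18), F_per_day = rgamma(20, 3)
  ))
  z2 <- zscore_features(m2)
  for (col in paste0("z_", attr(z2, "z_features"))) {
    expect_lt(abs(mean(z2[[col]])), 1e-9)
    expect_lt(abs(sd(z2[[col]]) - 1), 1e-9)
  }

  m2$F_per_day <- 7
  expect_error(zscore_features(m2), "F_per_day")
})

test_that("linear z-scoring of acrophase splits times around midnight", {
  # 23.5 h and 0.5 h are 1 h apart on the clock but z-score far apart;
  # documents the linear-acrophase convention used for clustering
  m <- make_metrics(data.frame(
    total_daily_sleep_min = c(100, 120, 110, 130),
    amplitude = c(10, 12, 11, 13),
    acrophase_h = c(23.5, 0.5, 23.4, 0.6),
    F_per_day = c(5, 6, 5.5, 6.5)
  ))
  z <- zscore_features(m)
  expect_gt(abs(z$z_acrophase_h[1] - z$z_acrophase_h[2]), 1.5)
})

test_that("k-means recovers well-separated blobs exactly", {
  skip_if_not_installed("mclust")
  set.seed(201)
  truth <- rep(1:3, each = 15)
  centers <- matrix(c(0, 0, 0, 0, 10, 10, 10, 10, -10, 10, -10, 10),
                    nrow = 3, byrow = TRUE)
  x <- centers[truth, ] + matrix(rnorm(45 * 4), 45, 4)
  m <- make_metrics(as.data.frame(setNames(
    as.data.frame(x),
    c("total_daily_sleep_min", "amplitude", "acrophase_h", "F_per_day")
  )))
  z <- zscore_features(m)
  cl <- kmeans_phenotype(z, k = 3, replicates = 50, seed = 1)
  ari <- mclust::adjustedRandIndex(cl$assignments$cluster, truth)
  expect_equal(ari, 1.0)
  # objective is recomputable from assignments + data
  zmat <- as.matrix(z[paste0("z_", cl$features)])
  recomputed <- sum(sapply(split(seq_len(45), cl$assignments$cluster), function(idx) {
    cen <- colMeans(zmat[idx, , drop = FALSE])
    sum(sweep(zmat[idx, , drop = FALSE], 2, cen)^2)
  }))
  expect_equal(cl$total_sum_distances, recomputed, tolerance = 1e-9)
})

test_that("duplicating every subject leaves the centroids unchanged", {
  set.seed(211)
  m <- make_metrics(data.frame(
    total_daily_sleep_min = rnorm(12, 300, 80), amplitude = rnorm(12, 100, 30),
    acrophase_h = runif(12, 10, 18), F_per_day = rgamma(12, 3)
  ))
  z1 <- zscore_features(m)
  # duplicate the feature rows themselves (weight invariance of the optimum)
  z2 <- dplyr::bind_rows(z1, dplyr::mutate(z1, subject_id = paste0(subject_id, "b")))
  attr(z2, "z_features") <- attr(z1, "z_features")
  c1 <- kmeans_phenotype(z1, k = 3, replicates = 100, seed = 5)
  c2 <- kmeans_phenotype(z2, k = 3, replicates = 100, seed = 5)
  expect_equal(as.data.frame(c1$centroids), as.data.frame(c2$centroids),
               tolerance = 1e-9)
  expect_equal(c2$total_sum_distances, 2 * c1$total_sum_distances,
               tolerance = 1e-9)
})

test_that("clusters are labelled A..C by ascending amplitude z-score", {
  set.seed(221)
  m <- make_metrics(data.frame(
    total_daily_sleep_min = rnorm(30, 300, 10),
    amplitude = c(rnorm(10, 20, 2), rnorm(10, 100, 2), rnorm(10, 500, 2)),
    acrophase_h = rnorm(30, 14, 0.2), F_per_day = rnorm(30, 10, 1)
  ))
  z <- zscore_features(m)
  cl <- kmeans_phenotype(z, k = 3, replicates = 100, seed = 2)
  joined <- augment(cl, z)
  means <- tapply(joined$amplitude, joined$cluster, mean)
  expect_identical(names(sort(means)), c("A", "B", "C"))
  z3 <- zscore_features(m[1:3, ])
  expect_error(kmeans_phenotype(z3, k = 3, replicates = 5, seed = 1), "smaller")
})

test_that("average actogram equals the loop oracle with equal subject weight", {
  set.seed(231)
  cohort <- lapply(c(2, 5, 3), function(d) make_days(rpois(d * 1440, 15)))
  act <- average_actogram(cohort)
  expect_identical(nrow(act), 1440L)
  # loop oracle
  want <- numeric(1440)
  for (dm in cohort) {
    prof <- numeric(1440)
    mat <- day_matrix(dm)
    for (mnt in 1:1440) prof[mnt] <- mean(mat[, mnt])
    want <- want + prof / length(cohort)
  }
  expect_equal(act$mean_counts, want, tolerance = 1e-12)
  # grand-mean conservation
  expect_equal(mean(act$mean_counts),
               mean(sapply(cohort, function(dm) mean(dm$counts))),
               tolerance = 1e-12)

  # one subject with identical days reproduces the day
  day <- rpois(1440, 9)
  dm1 <- make_days(rep(day, 3))
  expect_equal(average_actogram(list(dm1))$mean_counts, as.numeric(day))

  # two subjects -> (p + q) / 2 regardless of day counts
  a <- make_days(rpois(2 * 1440, 5)); b <- make_days(rpois(6 * 1440, 5))
  pq <- average_actogram(list(a, b))$mean_counts
  expect_equal(pq, (subject_profile_oracle(a) + subject_profile_oracle(b)) / 2)

  # mixed epoch lengths are rejected
  c30 <- make_days(rpois(2880, 5), epoch_seconds = 30)
  expect_error(average_actogram(list(a, c30)), "mixed epoch")
})

test_that("30 s epochs are averaged in within-minute pairs", {
  x <- rep(c(4L, 8L), 2880 / 2) # alternating within each minute
  dm <- make_days(x, epoch_seconds = 30)
  act <- average_actogram(list(dm))
  expect_equal(act$mean_counts, rep(6, 1440))
})

test_that("the two-stage smoother preserves constants and attenuates a cosine", {
  const <- rep(7.3, 1440)
  expect_equal(smooth_profile(const), const, tolerance = 1e-9)

  minute <- 0:1439
  cosine <- cos(2 * pi * minute / 1440)
  sm <- smooth_profile(cosine)
  # each circular moving-average pass multiplies the 24 h harmonic by
  # gain = sin(pi W / 1440) / (W sin(pi / 1440)); the quadratic stage
  # approximately restores it, so check stage 1 alone against the gain
  W <- 101
  gain <- sin(pi * W / 1440) / (W * sin(pi / 1440))
  stage1 <- as.numeric(stats::filter(cosine, rep(1 / W, W), sides = 2,
                                     circular = TRUE))
  fitted_amp <- 2 * mean(stage1 * cosine)
  expect_equal(fitted_amp, gain, tolerance = 1e-9)
  # full smoother keeps a pure harmonic shape: correlation ~ 1 with input
  expect_gt(cor(sm, cosine), 0.9999)

  # circular continuity: a ramp wraps without a jump at midnight
  ramp <- c(seq(0, 100, length.out = 720), seq(100, 0, length.out = 720))
  smr <- smooth_profile(ramp)
  interior_jump <- max(abs(diff(smr)))
  wrap_jump <- abs(smr[1] - smr[1440])
  expect_lt(wrap_jump, 5 * interior_jump)
})

test_that("compare_groups matches a hand-computed one-way ANOVA", {
  # textbook 3x3 toy: groups (1,2,3), (4,5,6), (7,8,9)
  # grand mean 5; SSB = 3*((2-5)^2+(5-5)^2+(8-5)^2) = 54; SSW = 6
  # F = (54/2)/(6/6) = 27, df = (2, 6)
  m <- tibble::tibble(group = rep(c("g1", "g2", "g3"), each = 3),
                      y = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  out <- compare_groups(m, "y")
  expect_equal(out$F, 27)
  expect_identical(c(out$df1, out$df2), c(2L, 6L))
  expect_equal(out$p_value, pf(27, 2, 6, lower.tail = FALSE))
  expect_identical(nrow(out$tukey), 3L)
  # the extreme pair has the smallest adjusted p
  expect_equal(unname(which.min(out$tukey$p_adj)),
               which(out$tukey$contrast == "g3-g1"))
  expect_error(compare_groups(m[1:3, ], "y"), "two groups")
})

test_that("Tukey flags exactly the pairs involving a shifted group", {
  set.seed(241)
  hits <- replicate(40, {
    m <- tibble::tibble(
      group = rep(c("a", "b", "c"), each = 20),
      y = c(rnorm(20), rnorm(20), rnorm(20, 3)) # c shifted by 3 sd
    )
    out <- compare_groups(m, "y")
    sig <- out$tukey$p_adj < 0.01
    names(sig) <- out$tukey$contrast
    unname(sig["b-a"] == FALSE && sig["c-a"] && sig["c-b"])
  })
  expect_gte(mean(hits), 0.95)
})
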