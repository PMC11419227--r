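#' Z-score the phenotype features within a clustering cohort
#'
#' Standardises the four RAR features used for phenotype clustering —
#' total daily "sleep", cosinor amplitude, acrophase and
#' duration-normalised pseudo-F — to mean 0 and sample standard deviation
#' 1 (n − 1 denominator) over the supplied cohort only. Acrophase is
#' z-scored linearly, not circularly: two subjects at 23.5 h and 0.5 h are
#' 23 linear hours apart despite a 1 h circular separation. This is the
#' convention the clustering procedure assumes; it is adequate when the
#' cohort's acrophases do not straddle midnight.
#'
#' @param metrics Per-subject metric tibble (from [cohort_metrics()]).
#' @param features Character vector of columns to z-score.
#' @return `metrics` with added `z_<feature>` columns and attribute
#'   `z_features`.
#' @export
zscore_features <- function(metrics,
                            features = c("total_daily_sleep_min", "amplitude",
                                         "acrophase_h", "F_per_day")) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 2)
  missing <- setdiff(features, names(metrics))
  if (length(missing)) {
    abort(sprintf("features not in metrics: %s", paste(missing, collapse = ", ")))
  }
  for (f in features) {
    s <- sd(metrics[[f]])
    if (!is.finite(s) || s == 0) {
      abort(sprintf("feature '%s' has zero standard deviation; cannot z-score.", f))
    }
    metrics[[paste0("z_", f)]] <- (metrics[[f]] - mean(metrics[[f]])) / s
  }
  attr(metrics, "z_features") <- features
  metrics
}

#' K-means RAR phenotype clustering
#'
#' Partitions subjects into `k` rest-activity phenotypes by k-means
#' (Lloyd's algorithm, squared Euclidean distance) on the z-scored feature
#' columns. Each of the `replicates` independent runs is initialised with
#' `k` distinct subjects sampled at random; the replicate with the lowest
#' total within-cluster sum of squared distances is returned. A replicate
#' that produces an empty cluster is retried with freshly sampled centers
#' (bounded retries).
#'
#' Cluster labels are ordered `A`, `B`, `C`, ... by ascending amplitude
#' z-score of the centroid, so `A` is always the weakest-rhythm phenotype.
#'
#' @param metrics Z-scored metric tibble from [zscore_features()].
#' @param k Number of clusters (default 3).
#' @param replicates Number of random initialisations (default 2000).
#' @param seed Integer seed (required, for reproducible replicate
#'   initialisation).
#' @param iter_max Lloyd iteration cap per replicate.
#' @return An object of class `rar_clusters`: list with `k`,
#'   `assignments` (tibble `subject_id`, `cluster`), `centroids` (tibble,
#'   one row per cluster, z-space), `total_sum_distances`, `replicates`,
#'   `seed`, `features`.
#' @export
kmeans_phenotype <- function(metrics, k = 3, replicates = 2000, seed,
                             iter_max = 100) {
  features <- attr(metrics, "z_features")
  if (is.null(features)) abort("metrics must come from zscore_features().")
  zcols <- paste0("z_", features)
  x <- as.matrix(metrics[zcols])
  n <- nrow(x)
  if (k >= n) abort("k must be smaller than the number of subjects.")

  best <- with_local_seed(seed, {
    best <- NULL
    for (r in seq_len(replicates)) {
      fit <- NULL
      for (attempt in 1:10) {
        centers <- x[sample.int(n, k), , drop = FALSE]
        if (anyDuplicated(centers)) next
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd")),
          error = function(e) NULL
        )
        if (!is.null(fit) && all(fit$size > 0)) break
        fit <- NULL
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
  if (is.null(best)) abort("k-means failed in every replicate.")

  # relabel clusters A, B, C, ... by ascending centroid amplitude z-score
  amp_col <- if ("z_amplitude" %in% zcols) "z_amplitude" else zcols[1]
  ord <- order(best$centers[, amp_col])
  relabel <- setNames(LETTERS[seq_len(k)], ord)
  cluster <- unname(relabel[as.character(best$cluster)])

  centroids <- tibble::as_tibble(best$centers[ord, , drop = FALSE])
  centroids$cluster <- LETTERS[seq_len(k)]
  centroids <- dplyr::relocate(centroids, "cluster")

  structure(
    list(
      k = k,
      assignments = tibble::tibble(subject_id = metrics$subject_id,
                                   cluster = cluster),
      centroids = centroids,
      total_sum_distances = best$tot.withinss,
      replicates = replicates,
      seed = seed,
      features = features
    ),
    class = "rar_clusters"
  )
}

#' @export
print.rar_clusters <- function(x, ...) {
  cat(sprintf(
    "k-means RAR phenotypes: k = %d, %d replicates (seed %d)\n  total sum of distances %.4f\n  sizes: %s\n",
    x$k, x$replicates, x$seed, x$total_sum_distances,
    paste(sprintf("%s=%d", names(table(x$assignments$cluster)),
                  table(x$assignments$cluster)), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname kmeans_phenotype
#' @param x An `rar_clusters` object.
#' @param ... Unused.
#' @export
tidy.rar_clusters <- function(x, ...) x$centroids

#' @rdname kmeans_phenotype
#' @export
glance.rar_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$k, total_sum_distances = x$total_sum_distances,
    replicates = x$replicates, seed = x$seed
  )
}

#' @rdname kmeans_phenotype
#' @param data The metric tibble the clustering was fitted on.
#' @export
augment.rar_clusters <- function(x, data, ...) {
  dplyr::left_join(data, x$assignments, by = "subject_id")
}

#' @export
autoplot.rar_clusters <- function(object, data = NULL, ...) {
  cen <- tidyr::pivot_longer(object$centroids, -"cluster",
                             names_to = "feature", values_to = "z")
  ggplot2::ggplot(cen, ggplot2::aes(.data$feature, .data$z,
                                    fill = .data$cluster)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "centroid z-score", fill = "cluster") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
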