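#' One-way ANOVA with Tukey HSD for a cohort metric
#'
#' Compares one per-subject metric across groups with an ordinary
#' (fixed-effects, pooled-variance) one-way ANOVA, followed by Tukey's
#' honestly-significant-difference test for all pairwise contrasts at the
#' pooled variance (studentized-range distribution; no Welch correction).
#'
#' @param metrics Per-subject tibble with a `group` column (e.g. from
#'   [cohort_metrics()], optionally after [augment()] with cluster labels
#'   via `group = cluster`).
#' @param metric Name of the metric column to compare (string).
#' @param group Name of the grouping column (default `"group"`).
#' @return An object of class `rar_anova`: list with `metric`, `F`,
#'   `df1`, `df2`, `p_value`, `group_means` (tibble), and `tukey` (tibble
#'   of pairwise contrasts: `contrast`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
#' @examples
#' m <- tibble::tibble(
#'   group = rep(c("a", "b", "c"), each = 4),
#'   amplitude = c(1, 2, 3, 2, 5, 6, 7, 6, 9, 10, 11, 10)
#' )
#' compare_groups(m, "amplitude")
compare_groups <- function(metrics, metric, group = "group") {
  stopifnot(is.data.frame(metrics), metric %in% names(metrics),
            group %in% names(metrics))
  df <- data.frame(
    y = metrics[[metric]],
    g = factor(metrics[[group]])
  )
  if (nlevels(df$g) < 2) abort("need at least two groups.")
  if (any(table(df$g) < 2)) abort("need at least two subjects per group.")
  if (sd(df$y) == 0) abort("degenerate variance: metric is constant.")

  fit <- aov(y ~ g, data = df)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g

  structure(
    list(
      metric = metric,
      F = s[["F value"]][1],
      df1 = as.integer(s[["Df"]][1]),
      df2 = as.integer(s[["Df"]][2]),
      p_value = s[["Pr(>F)"]][1],
      group_means = df |>
        dplyr::summarise(mean = mean(.data$y), sd = sd(.data$y),
                         n = dplyr::n(), .by = "g") |>
        dplyr::rename(group = "g"),
      tukey = tibble::tibble(
        contrast = rownames(tk),
        diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
        p_adj = tk[, "p adj"]
      )
    ),
    class = "rar_anova"
  )
}

#' @export
print.rar_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA on %s: F(%d, %d) = %.3g, p = %.3g\nTukey HSD:\n",
    x$metric, x$df1, x$df2, x$F, x$p_value
  ))
  print(as.data.frame(x$tukey), digits = 3)
  invisible(x)
}

#' @rdname compare_groups
#' @param x An `rar_anova` object.
#' @param ... Unused.
#' @export
tidy.rar_anova <- function(x, ...) x$tukey

#' @rdname compare_groups
#' @export
glance.rar_anova <- function(x, ...) {
  tibble::tibble(metric = x$metric, statistic = x$F,
                 df1 = x$df1, df2 = x$df2, p_value = x$p_value)
}
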