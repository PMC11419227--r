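#' Fit the single-component 24 h cosinor
#'
#' The cosinor is the classical parametric description of a rest-activity
#' rhythm: ordinary least squares of
#' \deqn{y(t) = M + \beta \cos(2\pi t/24) + \gamma \sin(2\pi t/24)}
#' on the epoch-level counts, with `t` in clock hours since the first
#' retained midnight. The linearised coefficients map to the rhythm
#' parameters
#' \deqn{A = \sqrt{\beta^2+\gamma^2}, \quad
#'       \phi = \frac{24}{2\pi}\,\mathrm{atan2}(\gamma, \beta) \bmod 24,}
#' so the fitted curve is \eqn{M + A\cos(2\pi (t-\phi)/24)}: `mesor` M is
#' the rhythm-adjusted mean, `amplitude` A half the peak-to-trough
#' excursion, and `acrophase` \eqn{\phi} the clock time (hours) of the
#' fitted peak. The period is fixed at 24 h ("standard cosinor"); the fit
#' is closed-form and deterministic.
#'
#' The fit uses counts at native epoch resolution, not hourly totals:
#' amplitude and acrophase are insensitive to the binning, and epoch-level
#' residuals keep `rss` on the same footing as the extended-cosine fit.
#'
#' @param dm An `rar_days` tibble from [trim_to_full_days()].
#' @return An object of class `cosinor_fit`: a list with elements `mesor`,
#'   `amplitude`, `acrophase` (hours in \[0, 24)), `rss`, `n`, `n_days`,
#'   `subject_id`.
#' @seealso [predict.cosinor_fit()], [fit_extended_cosine()]
#' @export
#' @examples
#' days <- trim_to_full_days(generate_subject(rar_preset("C"), seed = 1)$series)
#' fit <- fit_cosinor(days)
#' tidy(fit)
fit_cosinor <- function(dm) {
  assert_rar_days(dm)
  y <- dm$counts
  if (length(unique(y)) == 1L) {
    abort("degenerate cosinor: the signal is constant, acrophase is undefined.")
  }
  t <- (dm$day - 1) * 24 + dm$time_h
  w <- 2 * pi / 24
  fit <- lm(y ~ cos(w * t) + sin(w * t))
  b <- unname(coef(fit))
  amp <- sqrt(b[2]^2 + b[3]^2)
  phi <- (atan2(b[3], b[2]) / w) %% 24

  structure(
    list(
      mesor = b[1], amplitude = amp, acrophase = phi,
      rss = sum(fit$residuals^2), n = length(y),
      n_days = n_days(dm), subject_id = attr(dm, "subject_id")
    ),
    class = "cosinor_fit"
  )
}

#' Predict activity from a cosinor fit
#'
#' @param object A `cosinor_fit`.
#' @param t Clock time(s) in hours.
#' @param ... Unused.
#' @return Fitted mean counts per epoch at `t`:
#'   \eqn{M + A\cos(2\pi (t-\phi)/24)}.
#' @export
predict.cosinor_fit <- function(object, t, ...) {
  object$mesor + object$amplitude * cos(2 * pi * (t - object$acrophase) / 24)
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "24 h cosinor fit (%s, %d days, n = %d epochs)\n  mesor %.3f  amplitude %.3f  acrophase %.2f h\n",
    x$subject_id, x$n_days, x$n, x$mesor, x$amplitude, x$acrophase
  ))
  invisible(x)
}

#' @rdname fit_cosinor
#' @param x A `cosinor_fit`.
#' @param ... Unused.
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mesor", "amplitude", "acrophase"),
    estimate = c(x$mesor, x$amplitude, x$acrophase)
  )
}

#' @rdname fit_cosinor
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, mesor = x$mesor, amplitude = x$amplitude,
    acrophase_h = x$acrophase, rss = x$rss, n = x$n, n_days = x$n_days
  )
}

#' @export
autoplot.cosinor_fit <- function(object, ...) {
  grid <- tibble::tibble(
    t = seq(0, 24, by = 0.1),
    fitted = predict(object, seq(0, 24, by = 0.1))
  )
  ggplot2::ggplot(grid, ggplot2::aes(.data$t, .data$fitted)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$acrophase, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(
      x = "clock time (h)", y = "fitted counts / epoch",
      title = sprintf("Cosinor fit: %s", object$subject_id),
      subtitle = sprintf("mesor %.1f, amplitude %.1f, acrophase %.2f h",
                         object$mesor, object$amplitude, object$acrophase)
    )
}
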