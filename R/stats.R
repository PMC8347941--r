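#' Absolute measurement error
#'
#' Difference between a measured result and the true value of the measured
#' parameter (known only for simulations).
#'
#' @param measured Measured value(s).
#' @param true_value True value(s), same unit.
#' @return `measured - true_value`, vectorised.
#' @export
absolute_error <- function(measured, true_value) {
  stopifnot(is.numeric(measured), is.numeric(true_value),
            all(is.finite(measured)), all(is.finite(true_value)))
  measured - true_value
}

#' Student coefficient for a two-sided confidence interval
#'
#' Two-sided Student-t quantile at `n - 1` degrees of freedom and
#' confidence (probability) level `alpha`, i.e. `qt(1 - (1 - alpha)/2, df)`.
#' At 2 degrees of freedom and 0.95 the coefficient is 4.303.
#'
#' @param n Number of repeated measurements (>= 2).
#' @param alpha Confidence level. Default 0.95.
#' @return The coefficient, dimensionless.
#' @export
student_coefficient <- function(n, alpha = 0.95) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  stats::qt(1 - (1 - alpha) / 2, df = n - 1)
}

#' Measurement-series report: mean, deviation and random error
#'
#' Small-sample statistical evaluation of `n` repeats of the same
#' measurement: the arithmetic mean, the experimental standard deviation
#' (sigma, with `n - 1` in the denominator), the standard mean deviation
#' `S_md = sigma / sqrt(n)`, and the random error
#' `Delta = S_c * S_md` where `S_c` is the two-sided Student coefficient at
#' `n - 1` degrees of freedom and the given probability level. The final
#' result is expressed as mean +/- error.
#'
#' @param values Numeric vector of repeated measurements (`n >= 2`; with
#'   `n = 1` only the mean is defined and the error fields are `NA`).
#' @param alpha Confidence (probability) level. Default 0.95.
#' @param true_value Optional known true value; if given, the report also
#'   carries the absolute error of the mean.
#' @return An object of class `measurement_report`: list with `n`, `mean`,
#'   `sigma`, `s_md`, `student_coefficient`, `error`, `alpha`, `formatted`
#'   ("mean +/- error"), and optionally `absolute_error`.
#' @examples
#' series_report(c(1, 2, 3))  # sigma 1, S_md 0.577, error 2.48 at 0.95
#' @export
series_report <- function(values, alpha = 0.95, true_value = NULL) {
  stopifnot(is.numeric(values), length(values) >= 1, all(is.finite(values)))
  n <- length(values)
  m <- sum(values) / n
  if (n >= 2) {
    sigma <- sqrt(sum((values - m)^2) / (n - 1))
    s_md <- sigma / sqrt(n)
    s_c <- student_coefficient(n, alpha)
    err <- s_c * s_md
  } else {
    sigma <- s_md <- s_c <- err <- NA_real_
  }
  rep <- structure(
    list(n = n, mean = m, sigma = sigma, s_md = s_md,
         student_coefficient = s_c, error = err, alpha = alpha,
         formatted = sprintf("%.4g ± %.4g", m, err)),
    class = "measurement_report")
  if (!is.null(true_value))
    rep$absolute_error <- absolute_error(m, true_value)
  rep
}

#' @export
print.measurement_report <- function(x, ...) {
  cat(sprintf("Measurement report (n = %d, probability level %.2f)\n",
              x$n, x$alpha))
  cat(sprintf("  mean %.4g, sigma %.4g, S_md %.4g, S_c %.4g\n",
              x$mean, x$sigma, x$s_md, x$student_coefficient))
  cat(sprintf("  result: %s\n", x$formatted))
  if (!is.null(x$absolute_error))
    cat(sprintf("  absolute error of the mean: %.4g\n", x$absolute_error))
  invisible(x)
}

#' Summarise a gait-parameter table into per-group measurement reports
#'
#' Groups the tidy parameter table by any of the supplied grouping columns
#' present (e.g. parameter, channel, gait mode, repeat) and applies
#' [series_report()] to each group's values.
#'
#' @param params Data frame with a `value` column (e.g. rbind-ed
#'   `gait_parameters` from repeated recordings).
#' @param by Character vector of grouping column names. Default
#'   `c("mode", "parameter", "channel")`, silently reduced to the columns
#'   present.
#' @param alpha Confidence level for the random error.
#' @return Data frame with one row per group: grouping columns plus `n`,
#'   `mean`, `sigma`, `s_md`, `error`, and `formatted` ("mean +/- error").
#' @export
summarise_parameters <- function(params,
                                 by = c("mode", "parameter", "channel"),
                                 alpha = 0.95) {
  d <- as.data.frame(params)
  by <- intersect(by, names(d))
  stopifnot(length(by) > 0, "value" %in% names(d))
  groups <- split(d, d[by], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    r <- series_report(g$value, alpha = alpha)
    cbind(g[1L, by, drop = FALSE],
          data.frame(n = r$n, mean = r$mean, sigma = r$sigma, s_md = r$s_md,
                     error = r$error, formatted = r$formatted))
  }))
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}
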