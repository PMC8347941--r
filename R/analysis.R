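#' Analyse a gait recording
#'
#' The main entry point: detects loading pulses on all six channels,
#' extracts the gait parameters (amplitudes, stance durations, abruptness,
#' unevenness shifts), recovers the gait-phase fractions, aggregates a
#' gait signature, classifies the gait mode against the rulebook, and —
#' when a baseline is available — flags rhythm and asymmetry anomalies.
#'
#' @param recording A `gait_recording` (from [simulate_recording()] or
#'   [read_recording()]).
#' @param baseline Optional reference for anomaly flagging: a
#'   `gait_recording` of the same subject's normal gait, a
#'   `gait_signature`, or `NULL` to skip flagging.
#' @param rulebook Gait-mode rulebook; see [default_rulebook()].
#' @param thresholds Anomaly thresholds; see [flag_anomalies()].
#' @param alpha Confidence level used by [summary.gait_analysis()].
#' @param ... Detection threshold arguments passed to [detect_pulses()].
#' @return An object of class `gait_analysis` with components
#'   `parameters` (the `gait_parameters` table), `signature`, `phases`
#'   (from [phase_fractions()], or `NULL` if too few stances),
#'   `detection` (predicted mode, rule scores, anomaly flags and scores),
#'   and the `recording`.
#' @examples
#' rec <- simulate_recording("scrolling", n_steps = 5, seed = 2)
#' fit <- gait_analysis(rec)
#' fit
#' coef(fit)
#' @export
gait_analysis <- function(recording, baseline = NULL,
                          rulebook = default_rulebook(),
                          thresholds = list(rhythm_cv = 0.10,
                                            load_ratio = 0.25,
                                            phase_shift = 0.25),
                          alpha = 0.95, ...) {
  stopifnot(inherits(recording, "gait_recording"))
  params <- extract_gait_parameters(recording, ...)
  signature <- compute_signature(params)
  phases <- tryCatch(phase_fractions(params), error = function(e) NULL)
  cls <- classify_mode(signature, rulebook)
  base_sig <- if (inherits(baseline, "gait_recording"))
    compute_signature(extract_gait_parameters(baseline, ...))
  else baseline
  anomalies <- if (is.null(base_sig)) NULL
  else flag_anomalies(signature, base_sig, thresholds)
  structure(
    list(recording = recording, parameters = params, signature = signature,
         phases = phases,
         detection = list(predicted_mode = cls$predicted_mode,
                          scores = cls$scores,
                          anomalies = anomalies),
         alpha = alpha),
    class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat("Gait analysis\n")
  print(x$recording)
  cat(sprintf("  predicted gait mode: %s\n", x$detection$predicted_mode))
  if (!is.null(x$phases))
    cat(sprintf("  phases: stance %.1f%%, double support %.1f%%, swing %.1f%% of cycle (%.2f s)\n",
                100 * mean(x$phases$stance_fraction),
                100 * x$phases$double_support_fraction,
                100 * mean(x$phases$swing_fraction), x$phases$cycle))
  print(x$signature)
  if (!is.null(x$detection$anomalies)) {
    fl <- x$detection$anomalies$flags
    cat(sprintf("  anomaly flags: %s\n",
                if (length(fl)) paste(fl, collapse = ", ") else "none"))
  }
  invisible(x)
}

#' Per-channel measurement summary of a gait analysis
#'
#' Applies the repeated-measurement statistics (mean, sigma, standard mean
#' deviation, Student-t random error) to each parameter and channel across
#' steps.
#'
#' @param object A `gait_analysis`.
#' @param ... Unused.
#' @return Data frame from [summarise_parameters()].
#' @export
summary.gait_analysis <- function(object, ...) {
  summarise_parameters(object$parameters, by = c("parameter", "channel"),
                       alpha = object$alpha)
}

#' Mean extracted parameters per channel
#' @param object A `gait_analysis`.
#' @param ... Unused.
#' @return Named numeric vector `parameter.channel` of across-step means.
#' @export
coef.gait_analysis <- function(object, ...) {
  d <- as.data.frame(object$parameters)
  d <- d[d$parameter %in% c("amplitude", "stance", "abruptness"), ]
  m <- tapply(d$value, list(d$parameter, d$channel), mean)
  out <- as.vector(t(m))
  names(out) <- as.vector(t(outer(rownames(m), colnames(m), paste, sep = ".")))
  out[!is.na(out)]
}

#' Plot traces with detected pulses
#' @param x A `gait_analysis`.
#' @param channels Channels to show. Default all six.
#' @param ... Unused.
#' @export
plot.gait_analysis <- function(x, channels = gait_channels(), ...) {
  rec <- x$recording
  pulses <- attr(x$parameters, "pulses")
  old <- graphics::par(mfrow = c(length(channels), 1),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ch in channels) {
    graphics::plot(rec$time, rec$voltages[, ch], type = "l",
                   ylab = ch, xlab = "")
    p <- pulses[pulses$channel == ch, ]
    if (nrow(p)) {
      graphics::abline(v = p$onset_time, col = "forestgreen", lty = 2)
      graphics::abline(v = p$offset_time, col = "firebrick", lty = 3)
    }
  }
  invisible(x)
}
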