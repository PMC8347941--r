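#' Simulate a six-channel in-shoe pressure recording
#'
#' Composes the full acquisition chain: gait timeline -> per-channel load
#' waveform -> piezoresistive sensor resistance -> voltage-divider output,
#' then adds Gaussian noise and a linear drift and clamps to
#' \[0, supply voltage\]. The returned object carries the generating
#' timeline and profile as ground truth for validation.
#'
#' @param mode One of [gait_modes()], or a [gait_mode_profile()] via
#'   `profile`.
#' @param cadence Gait cycles per second. Default 1 (1.0 s cycle).
#' @param n_steps Stances per foot (>= 1). Default 6.
#' @param phase_model A [gait_phase_model()].
#' @param electrical An [electrical_model()].
#' @param profile Optional [gait_mode_profile()] overriding the mode
#'   defaults.
#' @param sampling_rate Samples per second. Default 100 Hz, enough to
#'   resolve ~0.15 s timing contrasts with 15 samples.
#' @param noise_sd Additive Gaussian noise, volts (>= 0). Default 0.
#' @param drift Linear baseline drift, volts per second. Default 0.
#' @param rise_time,fall_time Load pulse edge durations, seconds.
#' @param seed Optional integer seed; identical seed and arguments give an
#'   identical recording.
#' @return An object of class `gait_recording`: list with `time` (seconds),
#'   `voltages` (matrix, one column per channel in canonical order),
#'   `sampling_rate`, and a `truth` list (timeline, profile, models).
#' @examples
#' rec <- simulate_recording("normal", n_steps = 4, seed = 1)
#' rec
#' @export
simulate_recording <- function(mode = "normal", cadence = 1, n_steps = 6,
                               phase_model = gait_phase_model(),
                               electrical = electrical_model(),
                               profile = NULL,
                               sampling_rate = 100,
                               noise_sd = 0, drift = 0,
                               rise_time = 0.15, fall_time = 0.15,
                               seed = NULL) {
  if (is.null(profile)) profile <- gait_mode_profile(mode)
  stopifnot(inherits(profile, "gait_mode_profile"),
            n_steps >= 1, noise_sd >= 0, sampling_rate > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tl <- build_gait_timeline(
    cadence, n_steps, phase_model,
    asymmetry = c(profile$stance_scale_left, profile$stance_scale_right),
    phase_offset = profile$phase_offset)
  cycle <- attr(tl, "cycle")
  duration <- max(tl$left$end, tl$right$end) + 0.25 * cycle
  n <- floor(duration * sampling_rate) + 1L
  t <- (seq_len(n) - 1L) / sampling_rate
  ch <- gait_channels()
  load <- matrix(0, nrow = n, ncol = 6L, dimnames = list(NULL, ch))
  for (j in seq_along(ch)) {
    foot <- if (startsWith(ch[j], "L")) tl$left else tl$right
    for (i in seq_len(nrow(foot))) {
      s <- foot$start[i]; e <- foot$end[i]
      idx <- which(t >= s & t <= e)
      if (!length(idx)) next
      load[idx, j] <- load[idx, j] + channel_load_waveform(
        profile, ch[j], (t[idx] - s) / (e - s),
        stance_duration = e - s,
        rise_time = rise_time, fall_time = fall_time)
    }
  }
  v <- load_voltage(load, electrical)
  dim(v) <- dim(load); dimnames(v) <- dimnames(load)
  if (noise_sd > 0) v <- v + matrix(stats::rnorm(length(v), 0, noise_sd),
                                    nrow = n)
  if (drift != 0) v <- v + drift * t
  v <- pmin(pmax(v, 0), electrical$supply_voltage)
  dim(v) <- c(n, 6L); dimnames(v) <- list(NULL, ch)
  structure(
    list(time = t, voltages = v, sampling_rate = sampling_rate,
         truth = list(mode = profile$mode, timeline = tl, profile = profile,
                      phase_model = phase_model, electrical = electrical,
                      cadence = cadence, n_steps = n_steps,
                      noise_sd = noise_sd, drift = drift,
                      rise_time = rise_time, fall_time = fall_time,
                      seed = seed)),
    class = "gait_recording")
}

#' Construct a gait recording from raw data
#'
#' @param voltages Numeric matrix with columns named by [gait_channels()]
#'   (any order; reordered to canonical).
#' @param sampling_rate Samples per second (> 0).
#' @param start_time Time of the first sample, seconds. Default 0.
#' @return A `gait_recording` object (without simulation ground truth).
#' @export
gait_recording <- function(voltages, sampling_rate, start_time = 0) {
  stopifnot(is.matrix(voltages), sampling_rate > 0)
  if (is.null(colnames(voltages)) ||
      !all(gait_channels() %in% colnames(voltages)))
    stop("`voltages` must have columns named L1, L2, L3, R1, R2, R3",
         call. = FALSE)
  voltages <- voltages[, gait_channels(), drop = FALSE]
  t <- start_time + (seq_len(nrow(voltages)) - 1L) / sampling_rate
  structure(list(time = t, voltages = voltages,
                 sampling_rate = sampling_rate, truth = NULL),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("Gait recording: %d samples x 6 channels at %g Hz (%.2f s)\n",
              nrow(x$voltages), x$sampling_rate,
              nrow(x$voltages) / x$sampling_rate))
  if (!is.null(x$truth))
    cat(sprintf("  simulated: mode '%s', %d steps per foot, cycle %.2f s, noise sd %g V\n",
                x$truth$mode, x$truth$n_steps, 1 / x$truth$cadence,
                x$truth$noise_sd))
  cat(sprintf("  voltage range: %.3f to %.3f V\n",
              min(x$voltages), max(x$voltages)))
  invisible(x)
}

#' @export
summary.gait_recording <- function(object, ...) {
  v <- object$voltages
  data.frame(channel = colnames(v),
             min = apply(v, 2, min),
             median = apply(v, 2, stats::median),
             max = apply(v, 2, max),
             row.names = NULL)
}

#' Plot the six voltage traces of a recording
#' @param x A `gait_recording`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gait_recording <- function(x, ...) {
  graphics::matplot(x$time, x$voltages, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "sensor voltage (V)", ...)
  graphics::legend("topright", legend = colnames(x$voltages),
                   col = seq_len(6), lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}
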