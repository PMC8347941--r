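#' Extract all gait parameters from a recording
#'
#' Runs pulse detection on every channel and assembles the per-step gait
#' parameter table: pulse amplitudes A (weight distribution), stance
#' durations S, stepping abruptness D (initial contact to full loading),
#' and the stepping unevenness shifts between paired left/right channels
#' (L1-R1, ..., R3-L3).
#'
#' @param recording A `gait_recording`.
#' @param ... Threshold arguments passed to [detect_pulses()]
#'   (`high_frac`, `low_frac`, `min_width`, `refine_frac`, `min_range`).
#' @return An object of class `gait_parameters`: a tidy data frame with
#'   columns `foot`, `channel`, `step_index`, `parameter` (one of
#'   "amplitude", "stance", "abruptness", "unevenness_LR",
#'   "unevenness_RL") and `value` (volts for amplitudes, seconds
#'   otherwise), with the detected pulses and sampling rate as attributes.
#' @examples
#' rec <- simulate_recording("normal", n_steps = 4, seed = 1)
#' params <- extract_gait_parameters(rec)
#' head(params)
#' @export
extract_gait_parameters <- function(recording, ...) {
  pulses <- detect_all_pulses(recording, ...)
  params <- rbind(extract_amplitudes(pulses),
                  extract_stance_durations(pulses),
                  extract_abruptness(pulses),
                  extract_unevenness(pulses))
  rownames(params) <- NULL
  structure(params,
            class = c("gait_parameters", "data.frame"),
            pulses = pulses,
            sampling_rate = recording$sampling_rate)
}

#' @export
print.gait_parameters <- function(x, ...) {
  cat(sprintf("Gait parameters: %d values (%d pulses)\n",
              nrow(x), nrow(attr(x, "pulses"))))
  means <- stats::aggregate(value ~ parameter + channel,
                            data = as.data.frame(x), FUN = mean)
  wide <- stats::reshape(means, idvar = "channel", timevar = "parameter",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

.per_step <- function(pulses, parameter, value) {
  if (nrow(pulses) == 0L)
    return(data.frame(foot = character(0), channel = character(0),
                      step_index = integer(0), parameter = character(0),
                      value = numeric(0)))
  ord <- order(pulses$channel, pulses$onset_time)
  p <- pulses[ord, ]
  v <- value[ord]
  step <- stats::ave(seq_len(nrow(p)), p$channel, FUN = seq_along)
  data.frame(foot = p$foot, channel = p$channel, step_index = step,
             parameter = parameter, value = v)
}

#' Per-step pulse amplitudes (weight distribution parameter A)
#' @param pulses Pulse table from [detect_all_pulses()].
#' @return Tidy data frame of per-step peak amplitudes in volts.
#' @export
extract_amplitudes <- function(pulses)
  .per_step(pulses, "amplitude", pulses$peak_amplitude)

#' Per-step stance durations (parameter S)
#' @param pulses Pulse table from [detect_all_pulses()].
#' @return Tidy data frame of per-step contact durations
#'   (offset - onset) in seconds.
#' @export
extract_stance_durations <- function(pulses)
  .per_step(pulses, "stance", pulses$offset_time - pulses$onset_time)

#' Per-step stepping abruptness (parameter D)
#'
#' Time from initial contact (pulse onset) to full loading (the pulse
#' first reaching 90% of its peak); short values indicate an abrupt,
#' confident foot placement.
#'
#' @param pulses Pulse table from [detect_all_pulses()].
#' @return Tidy data frame of per-step abruptness in seconds.
#' @export
extract_abruptness <- function(pulses)
  .per_step(pulses, "abruptness", pulses$full_load_time - pulses$onset_time)

#' Stepping unevenness shifts between paired left/right channels
#'
#' For each pulse on left channel k, the L-R shift is the onset of the next
#' right-channel-k pulse minus this pulse's onset (nearest subsequent
#' onset); the R-L shift is defined symmetrically. In a rhythmic symmetric
#' gait both directions are close to half a cycle; a systematic difference
#' between them signals rhythm disturbance.
#'
#' @param pulses Pulse table from [detect_all_pulses()].
#' @return Tidy data frame with parameters "unevenness_LR" (rows attributed
#'   to the left channel) and "unevenness_RL" (right channel), values in
#'   seconds.
#' @export
extract_unevenness <- function(pulses) {
  out <- list()
  for (k in 1:3) {
    lk <- sort(pulses$onset_time[pulses$channel == paste0("L", k)])
    rk <- sort(pulses$onset_time[pulses$channel == paste0("R", k)])
    if (!length(lk) && !length(rk)) next  # pair absent altogether
    if (!length(lk) || !length(rk)) {
      warning(sprintf("no pulses on one foot for sensor pair %d; shift column empty", k),
              call. = FALSE)
      next
    }
    shift_to_next <- function(from, to) {
      v <- vapply(from, function(t0) {
        nxt <- to[to > t0]
        if (length(nxt)) nxt[1] - t0 else NA_real_
      }, numeric(1))
      v[!is.na(v)]
    }
    lr <- shift_to_next(lk, rk)
    rl <- shift_to_next(rk, lk)
    if (length(lr))
      out[[length(out) + 1L]] <- data.frame(
        foot = "left", channel = paste0("L", k),
        step_index = seq_along(lr), parameter = "unevenness_LR", value = lr)
    if (length(rl))
      out[[length(out) + 1L]] <- data.frame(
        foot = "right", channel = paste0("R", k),
        step_index = seq_along(rl), parameter = "unevenness_RL", value = rl)
  }
  if (!length(out))
    return(data.frame(foot = character(0), channel = character(0),
                      step_index = integer(0), parameter = character(0),
                      value = numeric(0)))
  do.call(rbind, out)
}

#' Load-distribution summary and dominant sensors
#'
#' Mean pulse amplitude per channel, per-foot descending ranking, and the
#' dominant (highest mean amplitude) sensor of each foot. The dominant
#' sensor's identity characterises the gait mode (e.g. forefoot-dominant
#' when climbing stairs). Exact ties are broken towards the lower channel
#' index.
#'
#' @param params A `gait_parameters` table (or any tidy table containing
#'   "amplitude" rows).
#' @return List with `means` (named vector, volts), `ranking` (data frame
#'   `foot`, `channel`, `mean_amplitude`, `rank`), and `dominant`
#'   (named character vector, one channel per foot).
#' @export
load_distribution_summary <- function(params) {
  amp <- as.data.frame(params)
  amp <- amp[amp$parameter == "amplitude", ]
  if (!nrow(amp)) stop("no amplitude rows in `params`", call. = FALSE)
  means <- tapply(amp$value, amp$channel, mean)
  ranking <- do.call(rbind, lapply(c("left", "right"), function(f) {
    pre <- if (f == "left") "L" else "R"
    ch <- names(means)[startsWith(names(means), pre)]
    if (!length(ch)) return(NULL)
    ch <- ch[order(-means[ch], ch)]  # ties -> lower channel index first
    data.frame(foot = f, channel = ch, mean_amplitude = as.numeric(means[ch]),
               rank = seq_along(ch))
  }))
  dominant <- vapply(split(ranking, ranking$foot),
                     function(d) d$channel[d$rank == 1L], character(1))
  list(means = means, ranking = ranking, dominant = dominant)
}

#' Per-foot stance envelopes
#'
#' Merges each foot's channel pulses into aggregate stance intervals
#' (earliest onset to latest offset across the foot's channels for each
#' step), by taking the union of overlapping pulse intervals.
#'
#' @param pulses Pulse table from [detect_all_pulses()].
#' @return List with data frames `left` and `right` (`start`, `end` in
#'   seconds, one row per stance).
#' @export
foot_envelopes <- function(pulses) {
  env_one <- function(p) {
    if (nrow(p) == 0L)
      return(data.frame(start = numeric(0), end = numeric(0)))
    p <- p[order(p$onset_time), ]
    start <- p$onset_time[1]; end <- p$offset_time[1]
    out <- NULL
    for (i in seq_len(nrow(p))[-1]) {
      if (p$onset_time[i] <= end) end <- max(end, p$offset_time[i])
      else {
        out <- rbind(out, c(start, end))
        start <- p$onset_time[i]; end <- p$offset_time[i]
      }
    }
    out <- rbind(out, c(start, end))
    data.frame(start = out[, 1], end = out[, 2])
  }
  list(left = env_one(pulses[pulses$foot == "left", ]),
       right = env_one(pulses[pulses$foot == "right", ]))
}

#' Recover gait-phase fractions from detected pulses
#'
#' Estimates, per foot, the stance fraction (aggregate stance envelope
#' duration over the cycle duration), the swing fraction (its complement),
#' and the double-support fraction — the total time both feet are loaded
#' per cycle, computed as the overlap between the left and right stance
#' envelopes within whole cycles. The cycle duration is estimated from the
#' mean onset-to-onset interval of each foot's envelopes.
#'
#' @param x A `gait_recording`, a `gait_parameters` object, or a pulse
#'   table from [detect_all_pulses()].
#' @param ... Passed to [detect_all_pulses()] when `x` is a recording.
#' @return List with `stance_fraction` (named vector, left/right),
#'   `swing_fraction`, `double_support_fraction` (scalar), and `cycle`
#'   (seconds).
#' @export
phase_fractions <- function(x, ...) {
  pulses <- if (inherits(x, "gait_recording")) detect_all_pulses(x, ...)
            else if (inherits(x, "gait_parameters")) attr(x, "pulses")
            else x
  env <- foot_envelopes(pulses)
  if (nrow(env$left) < 2L || nrow(env$right) < 2L)
    stop("need at least two stances per foot to estimate phase fractions",
         call. = FALSE)
  cycle_l <- mean(diff(env$left$start))
  cycle_r <- mean(diff(env$right$start))
  cycle <- mean(c(cycle_l, cycle_r))
  stance <- c(left = mean(env$left$end - env$left$start) / cycle,
              right = mean(env$right$end - env$right$start) / cycle)
  # double support is measured over a whole number of cycles, anchored
  # midway between the two feet's first onsets so that no double-support
  # episode straddles the window boundary (avoids edge bias)
  t0 <- (env$left$start[1] + env$right$start[1]) / 2
  t_end <- min(max(env$left$end), max(env$right$end))
  n_cycles <- floor((t_end - t0) / cycle)
  if (n_cycles < 1L)
    stop("recording too short to measure double support", call. = FALSE)
  window <- c(t0, t0 + n_cycles * cycle)
  ds <- interval_overlap_total(env$left, env$right, window) /
    (n_cycles * cycle)
  list(stance_fraction = stance, swing_fraction = 1 - stance,
       double_support_fraction = ds, cycle = cycle)
}
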