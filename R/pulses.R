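#' Detect loading pulses on a single sensor channel
#'
#' Hysteresis thresholding on the channel's dynamic range, defined as the
#' 95th percentile minus the baseline (5th percentile — the sensors idle
#' near a nonzero divider voltage). A pulse is a run of samples above the
#' low threshold that contains at least one sample above the high
#' threshold. Runs separated by less than `min_width` are merged (noise can
#' briefly dip a pulse below the low threshold), and pulses shorter than
#' `min_width` are discarded.
#'
#' The hysteresis crossings are then refined to the true loading
#' boundaries: the onset is moved back to the last sample at or below
#' baseline + `refine_frac` of the range, and the offset forward to the
#' first such sample, so that on clean signals the pulse bounds recover the
#' underlying stance interval to within one sample. The full-load time is
#' the first sample reaching 90% of that pulse's peak amplitude.
#'
#' @param trace Numeric vector of voltages for one channel.
#' @param sampling_rate Samples per second.
#' @param high_frac,low_frac Hysteresis thresholds as fractions of the
#'   dynamic range, `0 < low_frac < high_frac < 1`. Defaults 0.2 / 0.1.
#' @param min_width Minimum pulse duration in seconds. Default 0.1.
#' @param refine_frac Boundary-refinement level as a fraction of the
#'   dynamic range. Default 0.01.
#' @param min_range Absolute floor (volts) on the dynamic range below which
#'   the channel is considered inactive and no pulses are returned.
#'   Default 0.05.
#' @param start_time Time of the first sample, seconds.
#' @param channel Optional channel label stored with each pulse.
#' @return Data frame with one row per pulse: `channel`, `onset_time`,
#'   `full_load_time`, `offset_time` (seconds), `peak_amplitude` (volts
#'   above baseline), satisfying onset <= full_load <= offset.
#' @examples
#' v <- c(rep(0, 20), rep(2, 60), rep(0, 20))
#' detect_pulses(v, sampling_rate = 100)
#' @export
detect_pulses <- function(trace, sampling_rate, high_frac = 0.2,
                          low_frac = 0.1, min_width = 0.1,
                          refine_frac = 0.01, min_range = 0.05,
                          start_time = 0, channel = NA_character_) {
  stopifnot(is.numeric(trace), length(trace) > 0, sampling_rate > 0)
  if (!(low_frac > 0 && low_frac < high_frac && high_frac < 1))
    stop("need 0 < low_frac < high_frac < 1", call. = FALSE)
  empty <- data.frame(channel = character(0), onset_time = numeric(0),
                      full_load_time = numeric(0), offset_time = numeric(0),
                      peak_amplitude = numeric(0))
  n <- length(trace)
  baseline <- stats::quantile(trace, 0.05, names = FALSE)
  rng <- stats::quantile(trace, 0.95, names = FALSE) - baseline
  if (rng < min_range) return(empty)  # flat / inactive channel
  # guard thresholds against the noise floor, estimated robustly from the
  # quiet (swing) portion of the trace; zero on clean signals
  noise <- stats::mad(trace[trace <= stats::quantile(trace, 0.45,
                                                     names = FALSE)])
  hi <- baseline + max(high_frac * rng, 5 * noise)
  lo <- baseline + max(low_frac * rng, 4 * noise)
  floor_lvl <- baseline + max(refine_frac * rng, 3 * noise)

  r <- rle(trace > lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (!nrow(seg)) return(empty)
  # merge runs separated by less than min_width, but only when the gap
  # itself stays loaded (above the refinement floor): a mid-pulse noise dip
  # merges, a spurious spike across a baseline gap does not
  gap <- min_width * sampling_rate
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) for (i in 2:nrow(seg)) {
    g1 <- merged[nrow(merged), 2] + 1L; g2 <- seg[i, 1] - 1L
    loaded_gap <- g1 > g2 ||
      stats::median(trace[g1:g2]) > floor_lvl
    if (seg[i, 1] - merged[nrow(merged), 2] < gap && loaded_gap)
      merged[nrow(merged), 2] <- seg[i, 2]
    else merged <- rbind(merged, seg[i, ])
  }
  out <- vector("list", nrow(merged))
  prev_end <- 0L
  for (i in seq_len(nrow(merged))) {
    i1 <- merged[i, 1]; i2 <- merged[i, 2]
    if (!any(trace[i1:i2] > hi)) next        # hysteresis: must cross high
    on <- i1
    while (on > prev_end + 1L && trace[on - 1L] > floor_lvl) on <- on - 1L
    if (on > 1L && trace[on - 1L] <= floor_lvl) on <- on - 1L
    off <- i2
    while (off < n && trace[off + 1L] > floor_lvl) off <- off + 1L
    if (off < n && trace[off + 1L] <= floor_lvl) off <- off + 1L
    if ((off - on) / sampling_rate < min_width) next
    seg_v <- trace[on:off]
    peak <- max(seg_v)
    fl <- on - 1L + which(seg_v >= baseline + 0.9 * (peak - baseline))[1]
    out[[i]] <- data.frame(channel = channel,
                           onset_time = start_time + (on - 1L) / sampling_rate,
                           full_load_time = start_time + (fl - 1L) / sampling_rate,
                           offset_time = start_time + (off - 1L) / sampling_rate,
                           peak_amplitude = peak - baseline)
    prev_end <- off
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Detect pulses on every channel of a recording
#'
#' @param recording A `gait_recording`.
#' @param ... Threshold arguments passed to [detect_pulses()].
#' @return Data frame of pulses across all channels, with columns as in
#'   [detect_pulses()] plus `foot`. Inactive channels contribute no rows.
#' @export
detect_all_pulses <- function(recording, ...) {
  stopifnot(inherits(recording, "gait_recording"))
  res <- lapply(gait_channels(), function(ch)
    detect_pulses(recording$voltages[, ch], recording$sampling_rate,
                  start_time = recording$time[1], channel = ch, ...))
  pulses <- do.call(rbind, res)
  pulses$foot <- ifelse(startsWith(pulses$channel, "L"), "left", "right")
  pulses
}
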