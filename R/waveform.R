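#' Per-channel load waveform within one stance phase
#'
#' Smooth raised-cosine rise / plateau / raised-cosine fall pulse. The
#' channel is loaded only inside its activation window (a sub-interval of
#' the stance given by the profile), rises to exactly its configured peak
#' load and returns to zero, so the load is zero at the stance boundaries
#' `t_in_stance = 0` and `1`. Front sensors rise more slowly than the heel
#' (loading rolls onto the forefoot), giving them the longest stepping
#' abruptness, as observed on real recordings.
#'
#' @param profile A [gait_mode_profile()].
#' @param channel One of [gait_channels()].
#' @param t_in_stance Position within the stance phase, dimensionless in
#'   \[0, 1\]; vectorised.
#' @param stance_duration Duration of this stance in seconds (converts the
#'   rise/fall times to stance fractions). Default 0.6.
#' @param rise_time,fall_time Base edge durations in seconds; each is capped
#'   at 45% of the channel's activation window.
#' @return Load in load units, same length as `t_in_stance`.
#' @export
channel_load_waveform <- function(profile, channel, t_in_stance,
                                  stance_duration = 0.6,
                                  rise_time = 0.15, fall_time = 0.15) {
  stopifnot(inherits(profile, "gait_mode_profile"))
  if (!channel %in% gait_channels())
    stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
  if (any(t_in_stance < 0 | t_in_stance > 1))
    stop("`t_in_stance` must lie in [0, 1]", call. = FALSE)
  peak <- profile$peaks[[channel]]
  win <- profile$windows[channel, ]
  width <- (win[2] - win[1]) * stance_duration  # seconds of activation
  rise_scale <- c("1" = 1.4, "2" = 1.2, "3" = 1.0)[[substr(channel, 2, 2)]]
  rf <- min(rise_time * rise_scale / width, 0.45)
  ff <- min(fall_time / width, 0.45)
  u <- (t_in_stance - win[1]) / (win[2] - win[1])
  load <- numeric(length(u))
  inside <- u > 0 & u < 1
  ui <- u[inside]
  shape <- ifelse(ui < rf, 0.5 * (1 - cos(pi * ui / rf)),
           ifelse(ui > 1 - ff, 0.5 * (1 - cos(pi * (1 - ui) / ff)), 1))
  load[inside] <- peak * shape
  load
}
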