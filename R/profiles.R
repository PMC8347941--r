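#' Supported gait modes
#'
#' The normal gait plus the six simulated abnormal-gait cases used to
#' exercise the method: turnaround, scrolling (shuffling), climbing
#' upstairs, climbing downstairs, climbing upstairs one step at a time,
#' and walking with one straight leg.
#'
#' @return Character vector of mode names, in the fixed order used for
#'   deterministic tie-breaking by the classifier.
#' @export
gait_modes <- function() {
  c("normal", "turnaround", "scrolling", "upstairs", "downstairs",
    "upstairs_one_by_one", "straight_leg")
}

# Per-mode defaults. Peak loads are in arbitrary load units, calibrated so
# that divider voltages show the field-typical contrasts: within-foot
# amplitude spread up to ~1.9 V, between-leg mean contrast up to ~0.7 V,
# and a ~0.3 s left-right unevenness imbalance for the straight-leg gait.
# Windows are (onset, offset) fractions of the stance during which each
# channel is loaded; at least one channel spans each stance boundary so the
# per-foot envelope equals the full stance phase.
.mode_defaults <- function(mode) {
  ch <- gait_channels()
  win_heel_first <- rbind(  # normal initial contact: heel, then forefoot
    L1 = c(0.10, 1.00), L2 = c(0.15, 0.95), L3 = c(0.00, 0.85),
    R1 = c(0.10, 1.00), R2 = c(0.15, 0.95), R3 = c(0.00, 0.85))
  win_fore_first <- rbind(  # abnormal: initial contact on sensor 2
    L1 = c(0.25, 0.80), L2 = c(0.00, 0.90), L3 = c(0.05, 1.00),
    R1 = c(0.25, 0.80), R2 = c(0.00, 0.90), R3 = c(0.05, 1.00))
  def <- switch(mode,
    normal = list(
      peaks = c(6, 6, 10, 6, 6, 10), windows = win_heel_first,
      scale_left = 1, scale_right = 1, phase_offset = NA),
    turnaround = list(  # pivot on left heel, support on right forefoot
      peaks = c(5, 3, 25, 2, 12, 3), windows = win_heel_first,
      scale_left = 1.05, scale_right = 0.95, phase_offset = NA),
    scrolling = list(  # shuffling: right forefoot dominant, right foot longer
      peaks = c(2, 2, 8, 25, 3, 2), windows = win_heel_first,
      scale_left = 0.90, scale_right = 1.15, phase_offset = NA),
    upstairs = list(   # forefoot-loaded on both feet
      peaks = c(14, 8, 4, 16, 8, 3), windows = win_fore_first,
      scale_left = 1, scale_right = 1, phase_offset = NA),
    downstairs = list(
      peaks = c(8, 12, 6, 15, 8, 5), windows = win_fore_first,
      scale_left = 1, scale_right = 1, phase_offset = NA),
    upstairs_one_by_one = list(  # left leads and carries the load
      peaks = c(22, 12, 8, 4, 4, 7), windows = win_heel_first,
      scale_left = 1.1, scale_right = 0.9, phase_offset = NA),
    straight_leg = list(  # left leg straight: left heel + right forefoot,
                          # delayed right onset -> ~0.3 s unevenness imbalance
      peaks = c(4, 3, 14, 2, 15, 6),
      windows = rbind(
        L1 = c(0.20, 0.90), L2 = c(0.00, 0.85), L3 = c(0.05, 1.00),
        R1 = c(0.25, 0.80), R2 = c(0.00, 0.90), R3 = c(0.05, 1.00)),
      scale_left = 1.10, scale_right = 0.85, phase_offset = 0.65),
    stop(sprintf("unknown gait mode '%s'", mode), call. = FALSE))
  names(def$peaks) <- ch
  def
}

#' Gait-mode load profile
#'
#' Per-channel peak loads, per-channel activation windows within the stance
#' phase, per-leg stance-duration multipliers and the phase offset of the
#' right foot, together defining how a given gait mode loads the six
#' sensors. Defaults encode the characteristic signatures of each mode:
#' e.g. the turnaround pivots on the left heel (L3) while supporting on the
#' right forefoot (R2); scrolling loads R1 hardest; the straight-leg gait
#' keeps the heel loaded longest and delays the right-foot onset.
#'
#' @param mode One of [gait_modes()].
#' @param peaks Optional named numeric vector of per-channel peak loads
#'   (load units, >= 0) overriding the mode default.
#' @param windows Optional 6 x 2 matrix of per-channel (onset, offset)
#'   stance fractions, rownames = channels.
#' @param stance_scale_left,stance_scale_right Per-leg stance-duration
#'   multipliers (dimensionless, > 0).
#' @param phase_offset Right-foot onset as a fraction of the cycle after
#'   the left-foot onset (0.5 = symmetric alternation); `NA` derives it
#'   from the gait-phase model at simulation time.
#' @return An object of class `gait_mode_profile`.
#' @export
gait_mode_profile <- function(mode = "normal", peaks = NULL, windows = NULL,
                              stance_scale_left = NULL,
                              stance_scale_right = NULL,
                              phase_offset = NULL) {
  if (length(mode) != 1L || !mode %in% gait_modes())
    stop(sprintf("unknown gait mode '%s'", paste(mode, collapse = ",")),
         call. = FALSE)
  def <- .mode_defaults(mode)
  if (!is.null(peaks)) {
    stopifnot(is.numeric(peaks), !is.null(names(peaks)),
              all(gait_channels() %in% names(peaks)))
    if (any(peaks < 0)) stop("peak loads must be non-negative", call. = FALSE)
    def$peaks <- peaks[gait_channels()]
  }
  if (!is.null(windows)) {
    stopifnot(is.matrix(windows), nrow(windows) == 6L, ncol(windows) == 2L,
              all(gait_channels() %in% rownames(windows)))
    stopifnot(all(windows[, 1] >= 0), all(windows[, 2] <= 1),
              all(windows[, 1] < windows[, 2]))
    def$windows <- windows[gait_channels(), , drop = FALSE]
  }
  if (!is.null(stance_scale_left)) def$scale_left <- stance_scale_left
  if (!is.null(stance_scale_right)) def$scale_right <- stance_scale_right
  if (!is.null(phase_offset)) def$phase_offset <- phase_offset
  stopifnot(def$scale_left > 0, def$scale_right > 0)
  if (!is.na(def$phase_offset))
    stopifnot(def$phase_offset > 0, def$phase_offset < 1)
  structure(
    list(mode = mode, peaks = def$peaks, windows = def$windows,
         stance_scale_left = def$scale_left,
         stance_scale_right = def$scale_right,
         phase_offset = def$phase_offset),
    class = "gait_mode_profile")
}

#' @export
print.gait_mode_profile <- function(x, ...) {
  cat(sprintf("Gait mode profile: %s\n", x$mode))
  cat("  peak loads (load units):\n")
  print(round(x$peaks, 2))
  cat(sprintf("  stance scale L/R: %.2f / %.2f, right-foot phase offset %.2f cycle\n",
              x$stance_scale_left, x$stance_scale_right, x$phase_offset))
  invisible(x)
}
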