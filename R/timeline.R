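#' Build the per-leg stance timeline of a gait sequence
#'
#' Lays out alternating left/right stance intervals over `n_steps` gait
#' cycles. Left-foot stances start at multiples of the cycle duration; the
#' right foot is offset by `phase_offset` of a cycle. By default the offset
#' is derived from the phase model: when the double-support fraction equals
#' the symmetric value `2 * stance_fraction - 1`, the right foot starts
#' half a cycle after the left and each cycle contains two equal
#' double-support episodes; when a larger double support is requested, the
#' right foot is shifted so that a single episode of exactly
#' `double_support_fraction * cycle` occurs each cycle.
#'
#' @param cadence Gait cycles per second (> 0); the cycle duration is
#'   `1 / cadence`. One cycle is a full left+right stride.
#' @param n_steps Number of stances per foot (>= 0).
#' @param phase_model A [gait_phase_model()].
#' @param asymmetry Length-2 numeric, per-leg stance-duration multipliers
#'   `c(left, right)`; both must be > 0.
#' @param phase_offset Right-foot onset as a fraction of the cycle after the
#'   left onset, in (0, 1), or `NULL`/`NA` (default) to derive it from the
#'   phase model as described above.
#' @return List with data frames `left` and `right`, each with columns
#'   `start` and `end` (seconds), one row per stance, plus attributes
#'   `cycle` (seconds) and `phase_model`.
#' @examples
#' tl <- build_gait_timeline(1, 4)
#' tl$left$end - tl$left$start  # 0.6 s stances by default
#' @export
build_gait_timeline <- function(cadence, n_steps,
                                phase_model = gait_phase_model(),
                                asymmetry = c(1, 1),
                                phase_offset = NULL) {
  if (!is.numeric(cadence) || length(cadence) != 1L || cadence <= 0)
    stop("`cadence` must be a single positive number (cycles per second)",
         call. = FALSE)
  if (!inherits(phase_model, "gait_phase_model"))
    stop("`phase_model` must be a gait_phase_model object", call. = FALSE)
  stopifnot(is.numeric(n_steps), length(n_steps) == 1L, n_steps >= 0,
            is.numeric(asymmetry), length(asymmetry) == 2L,
            all(asymmetry > 0))
  if (is.null(phase_offset) || is.na(phase_offset)) {
    sf <- phase_model$stance_fraction
    ds <- phase_model$double_support_fraction
    phase_offset <- if (ds <= 2 * sf - 1 + 1e-9) 0.5 else 1 + ds - sf
  }
  stopifnot(phase_offset > 0, phase_offset < 1)
  n_steps <- as.integer(n_steps)
  cycle <- 1 / cadence
  stance <- phase_model$stance_fraction * cycle
  leg <- function(t0, scale) {
    if (n_steps == 0L)
      return(data.frame(start = numeric(0), end = numeric(0)))
    start <- t0 + (seq_len(n_steps) - 1L) * cycle
    data.frame(start = start, end = start + stance * scale)
  }
  out <- list(left = leg(0, asymmetry[1]),
              right = leg(phase_offset * cycle, asymmetry[2]))
  attr(out, "cycle") <- cycle
  attr(out, "phase_offset") <- phase_offset
  attr(out, "phase_model") <- phase_model
  out
}

# Total overlap duration between two sets of [start, end) intervals,
# optionally clipped to a window. Used for double-support accounting.
interval_overlap_total <- function(a, b, window = NULL) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  clip <- function(iv) {
    if (is.null(window)) return(iv)
    iv$start <- pmax(iv$start, window[1])
    iv$end <- pmin(iv$end, window[2])
    iv[iv$end > iv$start, , drop = FALSE]
  }
  a <- clip(a); b <- clip(b)
  total <- 0
  for (i in seq_len(nrow(a))) {
    ov <- pmin(a$end[i], b$end) - pmax(a$start[i], b$start)
    total <- total + sum(ov[ov > 0])
  }
  total
}
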