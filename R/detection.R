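#' Aggregate gait parameters into a per-recording signature
#'
#' Deterministic reduction of the per-step parameter table to the
#' quantities inspected when judging a gait: the dominant sensor of each
#' foot, the between-feet amplitude ratio (left over right), the mean
#' stance-duration asymmetry, the per-sensor-pair unevenness imbalance
#' `|mean(L_k - R_k) - mean(R_k - L_k)|`, mean abruptness per channel, and
#' the step-period coefficient of variation (rhythm).
#'
#' @param params A `gait_parameters` object.
#' @return An object of class `gait_signature`: list with fields
#'   `dominant` (per foot), `amplitude_ratio`, `stance_asymmetry` (s),
#'   `shift_imbalance` (named by sensor pair, s), `abruptness` (named by
#'   channel, s), `step_cv` (dimensionless), and `n_steps` per foot.
#' @export
compute_signature <- function(params) {
  d <- as.data.frame(params)
  if (!nrow(d)) stop("empty parameter table", call. = FALSE)
  amp <- d[d$parameter == "amplitude", ]
  n_steps <- tapply(amp$step_index, amp$foot, max)
  if (length(n_steps) < 2L || any(n_steps < 2L))
    stop("need at least 2 steps per foot to compute a gait signature",
         call. = FALSE)
  dist <- load_distribution_summary(d)
  mean_amp <- tapply(amp$value, amp$foot, mean)
  st <- d[d$parameter == "stance", ]
  mean_st <- tapply(st$value, st$foot, mean)
  lr <- d[d$parameter == "unevenness_LR", ]
  rl <- d[d$parameter == "unevenness_RL", ]
  imb <- vapply(1:3, function(k) {
    a <- lr$value[lr$channel == paste0("L", k)]
    b <- rl$value[rl$channel == paste0("R", k)]
    if (!length(a) || !length(b)) return(NA_real_)
    abs(mean(a) - mean(b))
  }, numeric(1))
  names(imb) <- paste0("pair", 1:3)
  ab <- d[d$parameter == "abruptness", ]
  abrupt <- tapply(ab$value, ab$channel, mean)
  # step periods: consecutive per-foot stance-envelope onsets (robust to a
  # single channel missing a pulse)
  pulses <- attr(params, "pulses")
  periods <- if (!is.null(pulses)) {
    env <- foot_envelopes(pulses)
    c(diff(env$left$start), diff(env$right$start))
  } else {
    # fallback when only the tidy table is available: L-R plus R-L shifts
    # of the same pair reconstruct the cycle
    unlist(lapply(1:3, function(k) {
      a <- lr$value[lr$channel == paste0("L", k)]
      b <- rl$value[rl$channel == paste0("R", k)]
      m <- min(length(a), length(b))
      if (m) a[seq_len(m)] + b[seq_len(m)] else numeric(0)
    }))
  }
  step_cv <- if (length(periods) > 1 && mean(periods) > 0)
    stats::sd(periods) / mean(periods) else 0
  structure(
    list(dominant = dist$dominant,
         amplitude_ratio = as.numeric(mean_amp["left"] / mean_amp["right"]),
         stance_asymmetry = abs(as.numeric(mean_st["left"] - mean_st["right"])),
         shift_imbalance = imb,
         abruptness = abrupt,
         step_cv = step_cv,
         n_steps = n_steps),
    class = "gait_signature")
}

#' @export
print.gait_signature <- function(x, ...) {
  cat("Gait signature\n")
  cat(sprintf("  dominant sensors: left %s, right %s\n",
              x$dominant[["left"]], x$dominant[["right"]]))
  cat(sprintf("  amplitude ratio L/R: %.3f, stance asymmetry %.3f s, step CV %.3f\n",
              x$amplitude_ratio, x$stance_asymmetry, x$step_cv))
  cat(sprintf("  unevenness imbalance (s): %s\n",
              paste(sprintf("%s=%.3f", names(x$shift_imbalance),
                            x$shift_imbalance), collapse = ", ")))
  invisible(x)
}

#' Default gait-mode rulebook
#'
#' One row per gait mode: the expected dominant sensor of each foot, the
#' direction of the between-feet amplitude ratio ("left" when the left foot
#' carries visibly more load, "right", or "balanced"), and whether a
#' left-right unevenness imbalance is expected. Encoded as a data frame so
#' it can be edited and stored as CSV (see [read_rulebook()]).
#'
#' @return Data frame with columns `mode`, `dominant_left`,
#'   `dominant_right`, `ratio_dir`, `imbalance`. Row order is the fixed
#'   tie-breaking order of the classifier.
#' @export
default_rulebook <- function() {
  data.frame(
    mode = gait_modes(),
    dominant_left = c("L3", "L3", "L3", "L1", "L2", "L1", "L3"),
    dominant_right = c("R3", "R2", "R1", "R1", "R1", "R3", "R2"),
    ratio_dir = c("balanced", "left", "right", "balanced", "balanced",
                  "left", "balanced"),
    imbalance = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Classify the gait mode from a signature
#'
#' Nearest-pattern match against the rulebook: each candidate mode scores
#' 2 points per matching dominant sensor, 1 point for a matching amplitude-
#' ratio direction, and 2 points for a matching unevenness-imbalance state.
#' The highest-scoring mode wins; exact ties are broken by rulebook row
#' order (fixed mode order).
#'
#' @param signature A `gait_signature`.
#' @param rulebook Data frame as returned by [default_rulebook()].
#' @param ratio_band Half-width band around 1 within which the amplitude
#'   ratio counts as "balanced". Default 0.10.
#' @param imbalance_threshold Unevenness imbalance (seconds) above which
#'   the gait counts as rhythm-shifted; default 0.20, midway between the
#'   near-zero imbalance of a rhythmic gait and the ~0.3 s shift of a
#'   one-leg rhythm disturbance.
#' @return List with `predicted_mode`, `scores` (named, one per mode) and
#'   the observed `ratio_dir` / `imbalance` features.
#' @export
classify_mode <- function(signature, rulebook = default_rulebook(),
                          ratio_band = 0.10, imbalance_threshold = 0.20) {
  stopifnot(inherits(signature, "gait_signature"), is.data.frame(rulebook))
  r <- signature$amplitude_ratio
  obs_dir <- if (r > 1 + ratio_band) "left"
             else if (r < 1 - ratio_band) "right" else "balanced"
  imb_max <- suppressWarnings(max(signature$shift_imbalance, na.rm = TRUE))
  obs_imb <- is.finite(imb_max) && imb_max > imbalance_threshold
  scores <- vapply(seq_len(nrow(rulebook)), function(i) {
    2 * (signature$dominant[["left"]] == rulebook$dominant_left[i]) +
    2 * (signature$dominant[["right"]] == rulebook$dominant_right[i]) +
    1 * (obs_dir == rulebook$ratio_dir[i]) +
    2 * (obs_imb == rulebook$imbalance[i])
  }, numeric(1))
  names(scores) <- rulebook$mode
  list(predicted_mode = rulebook$mode[which.max(scores)],
       scores = scores, ratio_dir = obs_dir, imbalance = obs_imb)
}

#' Flag rhythm and asymmetry anomalies against a baseline
#'
#' Compares a gait signature with a reference (normal) signature of the
#' same subject and raises flags where the deviation exceeds its
#' threshold: `rhythm` when the step-period coefficient of variation grows
#' beyond `rhythm_cv`; `load_asymmetry` when the between-feet amplitude
#' ratio moves away from the baseline ratio by more than `load_ratio`
#' (relative); `phase_asymmetry` when the largest unevenness imbalance
#' grows by more than `phase_shift` seconds (default 0.25 s, between the
#' normal near-zero imbalance and the ~0.3 s shift typical of a one-leg
#' rhythm disturbance). Each rule's score is its deviation divided by its
#' threshold, so a flag is raised exactly when its score exceeds 1; flags
#' are empty iff all scores are at or below 1.
#'
#' @param signature A `gait_signature` for the recording under test.
#' @param baseline A `gait_signature` from a normal reference recording of
#'   the same subject, or `NULL` to fall back (with a warning) to
#'   population defaults (ratio 1, imbalance 0, CV 0).
#' @param thresholds Named list with elements `rhythm_cv`, `load_ratio`,
#'   `phase_shift`.
#' @return List with `flags` (character subset of `c("rhythm",
#'   "load_asymmetry", "phase_asymmetry")`) and `scores` (named numeric).
#' @export
flag_anomalies <- function(signature, baseline = NULL,
                           thresholds = list(rhythm_cv = 0.10,
                                             load_ratio = 0.25,
                                             phase_shift = 0.25)) {
  stopifnot(inherits(signature, "gait_signature"))
  imb_of <- function(s) {
    m <- suppressWarnings(max(s$shift_imbalance, na.rm = TRUE))
    if (is.finite(m)) m else 0
  }
  if (is.null(baseline)) {
    warning("no baseline signature supplied; using population defaults",
            call. = FALSE)
    base_ratio <- 1; base_imb <- 0; base_cv <- 0
  } else {
    stopifnot(inherits(baseline, "gait_signature"))
    base_ratio <- baseline$amplitude_ratio
    base_imb <- imb_of(baseline)
    base_cv <- baseline$step_cv
  }
  dev_rhythm <- max(0, signature$step_cv - base_cv)
  dev_load <- abs(signature$amplitude_ratio / base_ratio - 1)
  dev_phase <- max(0, imb_of(signature) - base_imb)
  scores <- c(rhythm = dev_rhythm / thresholds$rhythm_cv,
              load_asymmetry = dev_load / thresholds$load_ratio,
              phase_asymmetry = dev_phase / thresholds$phase_shift)
  list(flags = names(scores)[scores > 1], scores = scores)
}
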