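#' Gait-phase timing model
#'
#' Partition of one gait cycle (one full left+right stride) into the standing
#' and swing phases of each leg. In typical adult gait the stance phase takes
#' about 60% of the cycle, of which about 20% is double support (both feet
#' loaded) and 40% single support; the swing phase takes the remaining 40%.
#' These fractions are the defaults.
#'
#' @param stance_fraction Fraction of the cycle each foot spends loaded,
#'   in (0, 1). Default 0.60.
#' @param double_support_fraction Fraction of the cycle during which both
#'   feet are loaded, in (0, 1); must be smaller than `stance_fraction` and
#'   at least `2 * stance_fraction - 1` (the minimum implied by two equal
#'   stances sharing one cycle). When it exceeds that minimum the timeline
#'   shifts one foot off the symmetric half-cycle to realise it.
#'   Default 0.20, exactly the symmetric value for a 60% stance.
#' @return An object of class `gait_phase_model` with fields
#'   `stance_fraction`, `double_support_fraction` and `swing_fraction`
#'   (the complement of stance).
#' @examples
#' gait_phase_model()
#' gait_phase_model(stance_fraction = 0.5, double_support_fraction = 0.1)
#' @export
gait_phase_model <- function(stance_fraction = 0.60,
                             double_support_fraction = 0.20) {
  stopifnot(is.numeric(stance_fraction), length(stance_fraction) == 1L,
            is.numeric(double_support_fraction),
            length(double_support_fraction) == 1L)
  if (!(stance_fraction > 0 && stance_fraction < 1))
    stop("`stance_fraction` must lie strictly in (0, 1)", call. = FALSE)
  if (!(double_support_fraction > 0 && double_support_fraction < 1))
    stop("`double_support_fraction` must lie strictly in (0, 1)",
         call. = FALSE)
  if (double_support_fraction >= stance_fraction)
    stop("`double_support_fraction` must be smaller than `stance_fraction`",
         call. = FALSE)
  # with both feet in continuous ground contact, the both-feet-loaded time
  # per cycle is at least stance_L + stance_R - cycle; a smaller double
  # support would require shorter stances
  if (double_support_fraction < 2 * stance_fraction - 1 - 1e-9)
    stop("`double_support_fraction` cannot be below 2*stance_fraction - 1 ",
         "(the minimum implied by two stances in one cycle)", call. = FALSE)
  structure(
    list(stance_fraction = stance_fraction,
         double_support_fraction = double_support_fraction,
         swing_fraction = 1 - stance_fraction),
    class = "gait_phase_model")
}

#' @export
print.gait_phase_model <- function(x, ...) {
  cat("Gait phase model (fractions of one cycle)\n")
  cat(sprintf("  stance: %.0f%%   double support: %.0f%%   swing: %.0f%%\n",
              100 * x$stance_fraction, 100 * x$double_support_fraction,
              100 * x$swing_fraction))
  invisible(x)
}

#' Sensor layout of the instrumented shoe linings
#'
#' Six piezoresistive sensors, three per foot: sensors 1 and 2 under the
#' forefoot (medial and lateral), sensor 3 under the heel.
#'
#' @return An object of class `sensor_layout`: a data frame with columns
#'   `channel` (L1, L2, L3, R1, R2, R3 in canonical order), `foot`
#'   ("left"/"right") and `zone` ("front-medial", "front-lateral", "heel").
#' @export
sensor_layout <- function() {
  layout <- data.frame(
    channel = c("L1", "L2", "L3", "R1", "R2", "R3"),
    foot = rep(c("left", "right"), each = 3L),
    zone = rep(c("front-medial", "front-lateral", "heel"), 2L),
    stringsAsFactors = FALSE)
  class(layout) <- c("sensor_layout", "data.frame")
  layout
}

#' Canonical channel labels
#' @return Character vector `c("L1","L2","L3","R1","R2","R3")`.
#' @export
gait_channels <- function() c("L1", "L2", "L3", "R1", "R2", "R3")

#' Electrical readout model (voltage divider over a piezoresistive sensor)
#'
#' Each sensor is read through a voltage divider: a fixed reference resistor
#' in series with the sensor, whose resistance decreases under load. The
#' output voltage (across the reference resistor) therefore increases with
#' applied load. Reference resistance defaults to 200 ohms; supply voltage
#' defaults to 3.3 V, typical for the ESP32-class microcontrollers used in
#' wearable acquisition boards.
#'
#' The resistance-load law is a hyperbolic stand-in,
#' `R(load) = R0 / (1 + k * load / R0)`, strictly decreasing and positive;
#' load units are arbitrary (the method needs no force calibration).
#'
#' @param reference_resistance Reference resistor, ohms (> 0). Default 200.
#' @param supply_voltage Supply, volts. Default 3.3.
#' @param unloaded_resistance Sensor resistance at zero load, ohms.
#'   Default 2000, placing the idle output at 0.3 V — comfortably above
#'   the ADC floor so noise does not clip.
#' @param load_sensitivity Resistance-drop coefficient `k`, ohms per load
#'   unit. Default 4000 (so one load unit divides the resistance by 3).
#' @return An object of class `electrical_model`.
#' @export
electrical_model <- function(reference_resistance = 200,
                             supply_voltage = 3.3,
                             unloaded_resistance = 2000,
                             load_sensitivity = 4000) {
  stopifnot(is.numeric(reference_resistance), reference_resistance > 0,
            is.numeric(supply_voltage), supply_voltage > 0,
            is.numeric(unloaded_resistance), unloaded_resistance > 0,
            is.numeric(load_sensitivity), load_sensitivity >= 0)
  structure(
    list(reference_resistance = reference_resistance,
         supply_voltage = supply_voltage,
         unloaded_resistance = unloaded_resistance,
         load_sensitivity = load_sensitivity),
    class = "electrical_model")
}

#' @export
print.electrical_model <- function(x, ...) {
  cat("Voltage-divider readout model\n")
  cat(sprintf("  reference %g ohm, supply %g V, unloaded sensor %g ohm, sensitivity %g ohm per load unit\n",
              x$reference_resistance, x$supply_voltage,
              x$unloaded_resistance, x$load_sensitivity))
  invisible(x)
}

#' Sensor resistance under load
#'
#' Hyperbolic decreasing law `R0 / (1 + k * load / R0)`: equals the unloaded
#' resistance at zero load, strictly decreasing and strictly positive for
#' any finite load.
#'
#' @param load Applied load, arbitrary load units (>= 0); vectorised.
#' @param model An [electrical_model()].
#' @return Resistance in ohms, same length as `load`.
#' @export
sensor_resistance <- function(load, model = electrical_model()) {
  stopifnot(inherits(model, "electrical_model"), is.numeric(load))
  if (any(load < 0)) stop("`load` must be non-negative", call. = FALSE)
  model$unloaded_resistance /
    (1 + model$load_sensitivity * load / model$unloaded_resistance)
}

#' Voltage-divider output for a given sensor resistance
#'
#' `V_out = V_supply * R_ref / (R_ref + R_sensor)`: half the supply when the
#' sensor matches the reference resistor, tending to zero as the sensor
#' resistance grows (unloaded sensor), and to the full supply as it
#' collapses under load.
#'
#' @param resistance Sensor resistance, ohms (> 0); vectorised.
#' @param model An [electrical_model()].
#' @return Output voltage in volts.
#' @export
divider_voltage <- function(resistance, model = electrical_model()) {
  stopifnot(inherits(model, "electrical_model"), is.numeric(resistance))
  if (any(resistance <= 0))
    stop("`resistance` must be strictly positive", call. = FALSE)
  model$supply_voltage * model$reference_resistance /
    (model$reference_resistance + resistance)
}

#' Load to output voltage, composing the sensor and divider laws
#' @param load Applied load, load units (>= 0); vectorised.
#' @param model An [electrical_model()].
#' @return Output voltage in volts.
#' @export
load_voltage <- function(load, model = electrical_model()) {
  divider_voltage(sensor_resistance(load, model), model)
}
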