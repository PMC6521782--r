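#' Convert an amplitude to a decibel level
#'
#' `20 * log10(amplitude / reference)`, the field convention behind
#' P0-pk (re 1 uPa) and A0-pk (re 1 um/s^2).
#'
#' @param amplitude positive amplitude(s).
#' @param reference positive reference amplitude (same units).
#' @return dB level(s).
#' @examples
#' amplitude_db(1e6, 1) # 1 Pa re 1 uPa = 120 dB
#' @export
amplitude_db <- function(amplitude, reference = 1) {
  if (any(!is.finite(amplitude)) || any(amplitude <= 0))
    abort("amplitude_db: amplitude must be positive and finite",
          class = "pulsefish_domain_error")
  if (!is.finite(reference) || reference <= 0)
    abort("amplitude_db: reference must be positive and finite",
          class = "pulsefish_domain_error")
  20 * log10(amplitude / reference)
}

# energy (power-like) quantity to dB
energy_db <- function(energy, reference = 1) {
  10 * log10(energy / reference)
}

#' Calibrate a hydrophone voltage trace to sound pressure
#'
#' Applies a hydrophone receive sensitivity stated in dB re 1 V/uPa
#' (e.g. -170 dB for an HTI-96-MIN, -180 dB for a vector-sensor
#' hydrophone) plus any recorder gain:
#' `pressure_uPa = volts / 10^((sensitivity_db + gain_db) / 20)`.
#'
#' @param volts numeric voltage samples.
#' @param sensitivity_db hydrophone sensitivity (dB re 1 V/uPa).
#' @param gain_db additional recorder gain (dB), default 0.
#' @param sample_rate sampling rate (Hz).
#' @param start_time absolute time of the first sample (s).
#' @return A pressure [acoustic_trace()] in uPa.
#' @examples
#' calibrate_pressure(1, -170, sample_rate = 14400)$samples # 3.162e8 uPa
#' @export
calibrate_pressure <- function(volts, sensitivity_db, gain_db = 0,
                               sample_rate = 14400, start_time = 0) {
  if (!is.finite(sensitivity_db))
    abort("calibrate_pressure: sensitivity must be finite",
          class = "pulsefish_calibration_error")
  if (!is.finite(gain_db))
    abort("calibrate_pressure: gain must be finite",
          class = "pulsefish_calibration_error")
  p <- as.numeric(volts) / 10^((sensitivity_db + gain_db) / 20)
  acoustic_trace(p, sample_rate, start_time = start_time, kind = "pressure")
}

#' Calibrate accelerometer voltage channels to particle acceleration
#'
#' For a sensor with sensitivity `volts_per_g` (1 V/g for the cage
#' particle-motion sensor, g ~ 9.82 m/s^2):
#' `acceleration_um_s2 = volts / volts_per_g * g_value * 1e6`.
#'
#' @param volts numeric vector (one axis) or 3-column matrix (x, y, z).
#' @param volts_per_g sensitivity (V per g), strictly positive.
#' @param g_value local gravitational acceleration (m/s^2).
#' @param sample_rate sampling rate (Hz).
#' @param start_time absolute time of the first sample (s).
#' @return An [acoustic_trace()] in um/s^2 (`acceleration3` when given
#'   three channels, otherwise a single pressure-shaped channel is not
#'   allowed: pass a matrix for the 3-axis sensor or use the returned
#'   vector form for single-axis bench checks).
#' @examples
#' calibrate_acceleration(matrix(1, 1, 3), 1)$samples[1, ] # 9.82e6 um/s^2
#' @export
calibrate_acceleration <- function(volts, volts_per_g, g_value = 9.82,
                                   sample_rate = 14400, start_time = 0) {
  if (!is.finite(volts_per_g) || volts_per_g <= 0)
    abort("calibrate_acceleration: volts_per_g must be positive",
          class = "pulsefish_calibration_error")
  a <- volts / volts_per_g * g_value * 1e6
  if (is.matrix(volts)) {
    acoustic_trace(a, sample_rate, start_time = start_time,
                   kind = "acceleration3")
  } else {
    # single-axis bench calibration: return plain numeric um/s^2
    as.numeric(a)
  }
}
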