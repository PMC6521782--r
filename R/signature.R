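#' Synthetic airgun source signature at 1 m
#'
#' Stand-in source model for a small seismic airgun: an exponentially
#' damped primary oscillation followed by a train of decaying
#' bubble-pulse oscillations.  The waveform is normalized so its maximum
#' absolute value equals the configured zero-to-peak source level, and
#' with default parameters its energy is concentrated well below 500 Hz,
#' where airgun pulses carry most of their energy.
#'
#' @param config a [scene_config()].
#' @return An [acoustic_trace()] (pressure, uPa) of duration
#'   `config$pulse_duration` referenced to 1 m from the source.
#' @examples
#' sig <- airgun_signature(scene_config(sample_rate = 4800))
#' max(abs(sig$samples)) / 10^(220 / 20)
#' @export
airgun_signature <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  fs <- config$sample_rate
  n <- round(config$pulse_duration * fs)
  t <- (0:(n - 1)) / fs
  peak <- 10^(config$source_level_p0pk / 20) # uPa zero-to-peak at 1 m

  if (is.infinite(config$damping)) {
    # impulse limit: all energy in the first sample, no bubble train
    p <- c(peak, numeric(n - 1))
    return(acoustic_trace(p, fs, kind = "pressure"))
  }

  n_bubbles <- floor((config$pulse_duration - 1 / fs) / config$bubble_period)
  p <- numeric(n)
  for (k in 0:n_bubbles) {
    t0 <- k * config$bubble_period
    idx <- t >= t0
    tau <- t[idx] - t0
    # sine onset: pressure (and so particle acceleration) is continuous
    # at each pulse start
    p[idx] <- p[idx] + config$bubble_amplitude^k *
      exp(-config$damping * tau) * sin(2 * pi * config$primary_frequency * tau)
  }
  # raised-cosine fade over the final 5% so the truncated bubble train
  # ends smoothly (no spectral edge artifacts)
  n_fade <- max(2, round(0.05 * n))
  fade_idx <- (n - n_fade + 1):n
  p[fade_idx] <- p[fade_idx] *
    0.5 * (1 + cos(pi * seq(0, 1, length.out = n_fade)))
  p <- p * (peak / max(abs(p)))
  acoustic_trace(p, fs, kind = "pressure")
}

#' Propagate a source waveform to a receiver range
#'
#' Spherical spreading (amplitude scaled by `1 / range_m`, i.e.
#' `20 log10(range)` transmission loss) with a travel delay of
#' `range_m / sound_speed` carried exactly in the trace start time, so
#' the waveform samples at the reference distance of 1 m are returned
#' unchanged.  An optional single surface-reflection echo (delayed,
#' scaled copy) can be superposed to mimic the initial pulse followed by
#' reflections seen on cage hydrophones.
#'
#' @param source_trace pressure [acoustic_trace()] referenced to 1 m.
#' @param range_m source-receiver range (m), at least 1 (the reference
#'   distance).
#' @param water list with `density` (kg/m^3) and `sound_speed` (m/s).
#' @param surface_echo optional `list(delay_s=, coefficient=)`.
#' @return The received pressure [acoustic_trace()]; its onset is
#'   delayed by `range_m / sound_speed` relative to the source.
#' @examples
#' sig <- airgun_signature(scene_config(sample_rate = 4800))
#' rec <- propagate(sig, 100, list(density = 1027, sound_speed = 1480))
#' 20 * log10(max(abs(sig$samples)) / max(abs(rec$samples))) # 40 dB
#' rec$start_time # travel delay 100 / 1480 s
#' @export
propagate <- function(source_trace, range_m,
                      water = list(density = 1027, sound_speed = 1480),
                      surface_echo = NULL) {
  stopifnot(inherits(source_trace, "acoustic_trace"),
            source_trace$kind == "pressure")
  if (!is.finite(range_m) || range_m < 1)
    abort("propagate: range_m must be >= 1 m (spherical model reference distance)",
          class = "pulsefish_domain_error")
  fs <- source_trace$sample_rate
  p <- source_trace$samples / range_m
  if (!is.null(surface_echo)) {
    echo_n <- round(surface_echo$delay_s * fs)
    echo <- c(numeric(echo_n), p * surface_echo$coefficient)
    p <- c(p, numeric(echo_n)) + echo
  }
  acoustic_trace(p, fs,
                 start_time = source_trace$start_time +
                   range_m / water$sound_speed,
                 kind = "pressure")
}

#' Particle acceleration of a plane pressure wave
#'
#' Far-field plane-wave relation: the scalar particle acceleration along
#' the propagation direction is `a(t) = (dp/dt) / (rho c)`, distributed
#' over the x/y/z axes by the direction cosines of the propagation unit
#' vector (x and y horizontal, z vertical).  The time derivative is
#' evaluated spectrally, so pure tones map exactly to amplitude
#' `p0 * 2 pi f / (rho c)`.  With pressure in uPa the result is in
#' um/s^2 (the 1e-6 scale factors cancel).
#'
#' @param pressure_trace pressure [acoustic_trace()] (uPa).
#' @param unit_direction length-3 unit vector of propagation.
#' @param water list with `density` (kg/m^3) and `sound_speed` (m/s).
#' @return A 3-channel acceleration [acoustic_trace()] (um/s^2).
#' @export
plane_wave_acceleration <- function(pressure_trace, unit_direction,
                                    water = list(density = 1027,
                                                 sound_speed = 1480)) {
  stopifnot(inherits(pressure_trace, "acoustic_trace"),
            pressure_trace$kind == "pressure")
  u <- as.numeric(unit_direction)
  if (length(u) != 3 || sum(u^2) == 0)
    abort("plane_wave_acceleration: direction must be a non-zero 3-vector",
          class = "pulsefish_domain_error")
  if (abs(sqrt(sum(u^2)) - 1) > 1e-9)
    abort("plane_wave_acceleration: direction must be a unit vector (|u| = 1 within 1e-9)",
          class = "pulsefish_domain_error")
  if (!is.numeric(water$density) || water$density <= 0 ||
      !is.numeric(water$sound_speed) || water$sound_speed <= 0)
    abort("plane_wave_acceleration: density and sound_speed must be positive",
          class = "pulsefish_domain_error")
  dpdt <- spectral_derivative(pressure_trace$samples, pressure_trace$sample_rate)
  scalar <- dpdt / (water$density * water$sound_speed)
  acoustic_trace(cbind(scalar * u[1], scalar * u[2], scalar * u[3]),
                 pressure_trace$sample_rate,
                 start_time = pressure_trace$start_time,
                 kind = "acceleration3")
}

# d/dt via FFT; exact for band-limited periodic content, adequate for
# pulses that decay to ~0 at the segment edges.
spectral_derivative <- function(x, fs) {
  n <- length(x)
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k[n / 2 + 1] <- 0 # zero the unpaired Nyquist bin
  omega <- 2 * pi * k * fs / n
  Re(fft(fft(x) * (1i * omega), inverse = TRUE)) / n
}
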