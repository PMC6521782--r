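#' Zero-to-peak level of a segment
#'
#' The maximum absolute excursion from the (zero) baseline of a
#' band-passed segment, in dB: `20 log10(max|s| / reference)`.  For a
#' 3-axis acceleration segment, per-axis levels and the vector-magnitude
#' level are returned.
#'
#' @param segment an [acoustic_trace()] (band-passed).
#' @param reference amplitude reference (1 uPa or 1 um/s^2).
#' @return For pressure, a single dB value; for acceleration, a named
#'   vector `c(x, y, z, vector)`.
#' @export
zero_to_peak <- function(segment, reference = 1) {
  stopifnot(inherits(segment, "acoustic_trace"))
  ch <- trace_channels(segment)
  if (all(ch == 0))
    abort("zero_to_peak: all-zero segment has no definable level",
          class = "pulsefish_domain_error")
  if (segment$kind == "pressure") {
    amplitude_db(max(abs(ch)), reference)
  } else {
    amps <- c(apply(abs(ch), 2, max), max(sqrt(rowSums(ch^2))))
    # an axis orthogonal to the arrival can be identically zero
    out <- ifelse(amps > 0, 20 * log10(amps / reference), NA_real_)
    names(out) <- c("x", "y", "z", "vector")
    out
  }
}

# one-sided ESD of one channel; density_k = w_k |X_k|^2 dt^2 per Hz,
# w = 2 except DC and Nyquist; Parseval: sum(density) * df = sum(x^2) dt
esd_channel <- function(x, fs) {
  n <- length(x)
  X <- fft(x)
  dt <- 1 / fs
  half <- floor(n / 2)
  k <- 0:half
  w <- rep(2, half + 1)
  w[1] <- 1
  if (n %% 2 == 0) w[half + 1] <- 1
  list(frequency = k * fs / n, density = w * Mod(X[k + 1])^2 * dt^2,
       df = fs / n)
}

#' Exposure spectral density of a 1 s segment
#'
#' Full-segment DFT of the 1 s analysis window (rectangular taper),
#' giving native 1 Hz bins: the exposure spectral density (ESD) in
#' uPa^2 s/Hz (pressure) or (um/s^2)^2 s/Hz (acceleration).  Parseval
#' holds exactly: the bin sum times the 1 Hz bin width equals the
#' time-domain energy of the segment.
#'
#' @param segment an [acoustic_trace()] of exactly 1 s.
#' @return A tibble with column `frequency` (Hz, 1 Hz spacing) and, for
#'   pressure, `density`; for 3-axis acceleration, `x`, `y`, `z` and
#'   their bin-wise sum `total`.
#' @export
exposure_spectral_density <- function(segment) {
  stopifnot(inherits(segment, "acoustic_trace"))
  fs <- segment$sample_rate
  n <- trace_length(segment)
  if (n != round(fs))
    abort("exposure_spectral_density: segment must be exactly 1 s long",
          class = "pulsefish_contract_error")
  ch <- trace_channels(segment)
  if (segment$kind == "pressure") {
    e <- esd_channel(ch[, 1], fs)
    tibble(frequency = e$frequency, density = e$density)
  } else {
    es <- lapply(1:3, function(j) esd_channel(ch[, j], fs))
    tibble(frequency = es[[1]]$frequency,
           x = es[[1]]$density, y = es[[2]]$density, z = es[[3]]$density,
           total = es[[1]]$density + es[[2]]$density + es[[3]]$density)
  }
}

band_sum <- function(frequency, density, f_lo, f_hi, df = 1) {
  sel <- frequency >= f_lo - 1e-9 & frequency <= f_hi + 1e-9
  if (!any(sel))
    abort("empty integration band", class = "pulsefish_domain_error")
  sum(density[sel]) * df
}

#' Single-pulse sound exposure level from an ESD
#'
#' Integrates the pressure ESD bins over the analysis band (5--500 Hz,
#' where the airgun carries its energy) and expresses the result in dB
#' re 1 uPa^2 s.
#'
#' @param esd pressure ESD tibble from [exposure_spectral_density()].
#' @param f_lo,f_hi integration band (Hz), inclusive.
#' @return SELsp in dB re 1 uPa^2 s.
#' @export
sel_single_pulse <- function(esd, f_lo = 5, f_hi = 500) {
  if (!"density" %in% names(esd))
    abort("sel_single_pulse: expected a pressure ESD (column `density`)",
          class = "pulsefish_contract_error")
  energy_db(band_sum(esd$frequency, esd$density, f_lo, f_hi))
}

#' Single-pulse acceleration exposure level for the total field
#'
#' Sums the three accelerometer-axis ESDs bin-wise, then integrates over
#' the analysis band: AELsp for the total acceleration field in dB re
#' 1 (um/s^2)^2 s.  Accepts either the acceleration ESD tibble from
#' [exposure_spectral_density()] or three per-axis ESD tibbles.
#'
#' @param esd_x acceleration ESD tibble (columns `x`, `y`, `z`) or a
#'   per-axis ESD tibble with column `density`.
#' @param esd_y,esd_z per-axis ESD tibbles when `esd_x` is one too.
#' @param f_lo,f_hi integration band (Hz), inclusive.
#' @return AELsp (total field) in dB re 1 (um/s^2)^2 s.
#' @export
ael_single_pulse <- function(esd_x, esd_y = NULL, esd_z = NULL,
                             f_lo = 5, f_hi = 500) {
  if (is.null(esd_y)) {
    if (!all(c("x", "y", "z") %in% names(esd_x)))
      abort("ael_single_pulse: need columns x, y, z or three per-axis ESDs",
            class = "pulsefish_contract_error")
    total <- esd_x$x + esd_x$y + esd_x$z
    freq <- esd_x$frequency
  } else {
    if (!identical(esd_x$frequency, esd_y$frequency) ||
        !identical(esd_x$frequency, esd_z$frequency))
      abort("ael_single_pulse: per-axis ESDs must share identical bins",
            class = "pulsefish_contract_error")
    total <- esd_x$density + esd_y$density + esd_z$density
    freq <- esd_x$frequency
  }
  energy_db(band_sum(freq, total, f_lo, f_hi))
}

#' Cumulative exposure level over a pulse sequence
#'
#' Sums the per-pulse energies (`10^(L/10)`) and returns the running
#' cumulative level `10 log10(sum)`; discarded pulses contribute
#' nothing and carry the previous value forward.
#'
#' @param levels_db per-pulse single-pulse levels (dB).
#' @param discarded optional logical vector marking pulses to skip.
#' @return A tibble with `pulse`, `level_db`, `cumulative_db`; the final
#'   row holds the session SELcum/AELcum.
#' @export
cumulative_level <- function(levels_db, discarded = NULL) {
  if (length(levels_db) == 0)
    abort("cumulative_level: empty input", class = "pulsefish_domain_error")
  discarded <- discarded %||% rep(FALSE, length(levels_db))
  discarded <- discarded | !is.finite(levels_db)
  if (all(discarded))
    abort("cumulative_level: no retained pulses", class = "pulsefish_domain_error")
  e <- ifelse(discarded, 0, 10^(levels_db / 10))
  run <- cumsum(e)
  tibble(pulse = seq_along(levels_db), level_db = levels_db,
         discarded = discarded,
         cumulative_db = ifelse(run > 0, 10 * log10(run), NA_real_))
}

#' Root-mean-square level series
#'
#' rms pressure in consecutive fixed-length intervals (1 s by default),
#' in dB re the amplitude reference — the standard ambient-level view of
#' a long recording.
#'
#' @param trace an [acoustic_trace()] (pressure).
#' @param interval interval length (s).
#' @param reference amplitude reference.
#' @return A tibble with `time` (interval start, s) and `rms_db`.
#' @export
rms_level_series <- function(trace, interval = 1, reference = 1) {
  stopifnot(inherits(trace, "acoustic_trace"))
  fs <- trace$sample_rate
  len <- round(interval * fs)
  n_int <- floor(trace_length(trace) / len)
  if (n_int < 1)
    abort("rms_level_series: interval longer than trace",
          class = "pulsefish_contract_error")
  x <- trace_channels(trace)[, 1]
  ms <- vapply(seq_len(n_int), function(i) {
    mean(x[((i - 1) * len + 1):(i * len)]^2)
  }, numeric(1))
  tibble(time = trace$start_time + (seq_len(n_int) - 1) * interval,
         rms_db = 10 * log10(ms / reference^2))
}

#' Band-limited energy series (spectrogram band integral)
#'
#' Splits the trace into windows, computes each window's ESD and
#' integrates 5--500 Hz, giving the energy-versus-time curve used to
#' visualize airgun shots against background noise.
#'
#' @param trace an [acoustic_trace()] (pressure).
#' @param f_lo,f_hi integration band (Hz).
#' @param window window length (s).
#' @param hop hop between window starts (s), default no overlap.
#' @return A tibble with `time` (window start, s) and `energy_db`
#'   (dB re 1 uPa^2 s per window).
#' @export
band_energy_series <- function(trace, f_lo = 5, f_hi = 500,
                               window = 1, hop = window) {
  stopifnot(inherits(trace, "acoustic_trace"))
  fs <- trace$sample_rate
  wlen <- round(window * fs)
  hlen <- max(1, round(hop * fs))
  n <- trace_length(trace)
  if (wlen > n)
    abort("band_energy_series: window longer than trace",
          class = "pulsefish_contract_error")
  starts <- seq(1, n - wlen + 1, by = hlen)
  x <- trace_channels(trace)[, 1]
  vals <- vapply(starts, function(i) {
    e <- esd_channel(x[i:(i + wlen - 1)], fs)
    band_sum(e$frequency, e$density, f_lo, f_hi, df = e$df)
  }, numeric(1))
  tibble(time = trace$start_time + (starts - 1) / fs,
         energy_db = 10 * log10(vals))
}
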