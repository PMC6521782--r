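finite_or_na <- function(x) ifelse(is.finite(x), x, NA_real_)

safe_z2p <- function(segment, reference = 1) {
  tryCatch(zero_to_peak(segment, reference),
           pulsefish_domain_error = function(e) NA_real_)
}

# metrics for one selected (and transient-screened) shot window pair
one_shot_metrics <- function(win_p, win_a, band = c(5, 500),
                             full_scale = NULL) {
  clipped <- !is.null(full_scale) && is_clipped(win_p$exposure, full_scale)
  row <- tibble(
    time = win_p$shot_time, peak_offset = win_p$peak_offset,
    discarded = win_p$discarded, reason = win_p$reason, clipped = clipped,
    p0pk_db = NA_real_, selsp_db = NA_real_,
    a0pk_db = NA_real_, aelsp_db = NA_real_,
    aelsp_x_db = NA_real_, aelsp_y_db = NA_real_, aelsp_z_db = NA_real_,
    bg_p0pk_db = NA_real_, bg_selsp_db = NA_real_,
    bg_a0pk_db = NA_real_, bg_aelsp_db = NA_real_
  )
  esd_p <- exposure_spectral_density(win_p$exposure)
  esd_p_bg <- exposure_spectral_density(win_p$background)
  row$p0pk_db <- safe_z2p(win_p$exposure)
  row$bg_p0pk_db <- safe_z2p(win_p$background)
  row$selsp_db <- finite_or_na(sel_single_pulse(esd_p, band[1], band[2]))
  row$bg_selsp_db <- finite_or_na(sel_single_pulse(esd_p_bg, band[1], band[2]))
  if (!is.null(win_a)) {
    esd_a <- exposure_spectral_density(win_a$exposure)
    esd_a_bg <- exposure_spectral_density(win_a$background)
    z <- safe_z2p(win_a$exposure)
    row$a0pk_db <- if (all(is.na(z))) NA_real_ else unname(z["vector"])
    zb <- safe_z2p(win_a$background)
    row$bg_a0pk_db <- if (all(is.na(zb))) NA_real_ else unname(zb["vector"])
    row$aelsp_db <- finite_or_na(ael_single_pulse(esd_a, f_lo = band[1],
                                                  f_hi = band[2]))
    row$bg_aelsp_db <- finite_or_na(ael_single_pulse(esd_a_bg, f_lo = band[1],
                                                     f_hi = band[2]))
    for (ax in c("x", "y", "z")) {
      row[[paste0("aelsp_", ax, "_db")]] <- finite_or_na(
        energy_db(band_sum(esd_a$frequency, esd_a[[ax]], band[1], band[2])))
    }
    if (win_a$discarded && !row$discarded) {
      row$discarded <- TRUE
      row$reason <- win_a$reason
    }
  }
  row
}

append_cumulative <- function(metrics) {
  skip <- metrics$discarded | metrics$clipped
  if (all(skip | !is.finite(metrics$selsp_db))) {
    metrics$selcum_db <- NA_real_
    metrics$aelcum_db <- NA_real_
    return(metrics)
  }
  metrics$selcum_db <-
    cumulative_level(ifelse(is.na(metrics$selsp_db), -Inf, metrics$selsp_db),
                     discarded = skip)$cumulative_db
  metrics$aelcum_db <- if (all(is.na(metrics$aelsp_db))) NA_real_ else
    cumulative_level(ifelse(is.na(metrics$aelsp_db), -Inf, metrics$aelsp_db),
                     discarded = skip)$cumulative_db
  metrics
}

#' Per-pulse exposure metrics from continuous calibrated traces
#'
#' Runs the full per-shot analysis chain on a calibrated recording:
#' band-pass filtering (5--1000 Hz third-order Butterworth), 1 s pulse
#' window selection with the peak within 200 ms of the window start, a
#' 1 s background window 1--2 s before the pulse, transient screening,
#' zero-to-peak levels, 1 Hz exposure spectral densities integrated over
#' 5--500 Hz (SELsp / AELsp, per axis and total field), and running
#' cumulative levels over the retained pulses.
#'
#' @param pressure calibrated pressure [acoustic_trace()] (uPa).
#' @param acceleration optional 3-axis acceleration [acoustic_trace()]
#'   (um/s^2) recorded alongside.
#' @param shots shot log tibble with `shot_id`, `fire_time` and
#'   optionally `range_m` (then arrival = fire + range / c), or an
#'   `arrival_time` column used directly.
#' @param sound_speed sound speed for travel-time conversion (m/s).
#' @param band SEL/AEL integration band (Hz).
#' @param filter_band band-pass filter edges (Hz).
#' @param threshold_ratio background transient rejection ratio, see
#'   [reject_transient()].
#' @param max_peak_offset latest admissible peak position (s).
#' @param full_scale optional full-scale magnitude (uPa); pulses with 3+
#'   consecutive saturated samples are flagged `clipped` and excluded
#'   from cumulative sums.
#' @param zero_phase use zero-phase filtering (see [bandpass()]).
#' @return A tibble, one row per shot: identification (`shot_id`,
#'   `time`), `p0pk_db`, `selsp_db`, `a0pk_db`, `aelsp_db`,
#'   `aelsp_x/y/z_db`, background counterparts (`bg_*`), running
#'   `selcum_db` / `aelcum_db`, `discarded`, `reason`, `clipped`.
#' @export
pulse_metrics <- function(pressure, acceleration = NULL, shots,
                          sound_speed = 1480, band = c(5, 500),
                          filter_band = c(5, 1000), threshold_ratio = 10,
                          max_peak_offset = 0.2, full_scale = NULL,
                          zero_phase = FALSE) {
  stopifnot(inherits(pressure, "acoustic_trace"))
  if (nrow(shots) == 0)
    abort("pulse_metrics: empty shot log", class = "pulsefish_domain_error")
  arrivals <- if ("arrival_time" %in% names(shots)) shots$arrival_time
  else if ("range_m" %in% names(shots))
    shots$fire_time + shots$range_m / sound_speed
  else shots$fire_time
  p_f <- bandpass(pressure, filter_band[1], filter_band[2],
                  zero_phase = zero_phase)
  a_f <- if (!is.null(acceleration))
    bandpass(acceleration, filter_band[1], filter_band[2],
             zero_phase = zero_phase)
  rows <- map(seq_len(nrow(shots)), function(i) {
    win_p <- select_pulse_window(p_f, arrivals[i],
                                 max_peak_offset = max_peak_offset)
    win_p <- reject_transient(win_p, threshold_ratio)
    win_a <- NULL
    if (!is.null(a_f)) {
      t0 <- win_p$exposure$start_time
      win_a <- structure(
        list(exposure = trace_slice(a_f, t0, t0 + 1),
             background = trace_slice(a_f, t0 - 2, t0 - 1),
             peak_offset = win_p$peak_offset, shot_time = arrivals[i],
             discarded = FALSE, reason = NA_character_),
        class = "pulse_window")
      win_a <- reject_transient(win_a, threshold_ratio)
    }
    one_shot_metrics(win_p, win_a, band = band, full_scale = full_scale)
  })
  out <- bind_rows(rows)
  out <- bind_cols(tibble(shot_id = shots$shot_id), out)
  append_cumulative(out)
}

#' Per-pulse metrics for a simulated session, shot by shot
#'
#' Memory-bounded driver for long transects: instead of synthesizing a
#' continuous multi-hour trace, each shot's received pulse (plus local
#' ambient noise) is generated, analysed, and released.  Output matches
#' [pulse_metrics()].
#'
#' @param scene a [scene_config()].
#' @param shots shot log from [simulate_shot_log()].
#' @param noise include ambient noise.
#' @param seed RNG seed; defaults to `scene$seed`.
#' @inheritParams pulse_metrics
#' @return A per-pulse metrics tibble as from [pulse_metrics()].
#' @export
pulse_metrics_from_scene <- function(scene, shots, noise = TRUE, seed = NULL,
                                     band = c(5, 500),
                                     filter_band = c(5, 1000),
                                     threshold_ratio = 10,
                                     max_peak_offset = 0.2,
                                     full_scale = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  if (nrow(shots) == 0)
    abort("pulse_metrics_from_scene: empty shot log",
          class = "pulsefish_domain_error")
  set.seed(seed %||% scene$seed)
  fs <- scene$sample_rate
  c_ms <- scene$sound_speed_ms
  pre <- 3.4; post <- 1.7
  sig_cache <- list()
  asc_cache <- list()
  rows <- map(seq_len(nrow(shots)), function(i) {
    lev <- as.character(shots$source_level_db[i])
    if (is.null(sig_cache[[lev]])) {
      sig_cache[[lev]] <<- airgun_signature(
        scene_with_level(scene, shots$source_level_db[i]))
      asc_cache[[lev]] <<- spectral_derivative(
        sig_cache[[lev]]$samples, fs) /
        (scene$water_density * scene$sound_speed_ms)
    }
    arrival <- shots$fire_time[i] + shots$range_m[i] / c_ms
    n <- round((pre + post) * fs)
    t0 <- arrival - pre
    p <- if (noise) ambient_noise(n, fs, scene$ambient_level_rms)
         else numeric(n)
    a <- if (noise)
      matrix(rnorm(3 * n), ncol = 3) *
        10^(scene$ambient_accel_level_rms / 20) / sqrt(3)
    else matrix(0, n, 3)
    rp <- received_pulse(scene, shots$range_m[i],
                         c(shots$x[i], shots$y[i], shots$z[i]),
                         fire_time = shots$fire_time[i],
                         signature = sig_cache[[lev]],
                         accel_scalar = asc_cache[[lev]])
    i0 <- round((shots$fire_time[i] - t0) * fs) + 1
    idx <- i0:(i0 + trace_length(rp$pressure) - 1)
    keep <- idx >= 1 & idx <= n
    p[idx[keep]] <- p[idx[keep]] + rp$pressure$samples[keep]
    a[idx[keep], ] <- a[idx[keep], ] + rp$acceleration$samples[keep, ]
    pm <- pulse_metrics(
      acoustic_trace(p, fs, start_time = t0, kind = "pressure"),
      acoustic_trace(a, fs, start_time = t0, kind = "acceleration3"),
      shots = tibble(shot_id = shots$shot_id[i],
                     fire_time = shots$fire_time[i],
                     range_m = shots$range_m[i]),
      sound_speed = c_ms, band = band, filter_band = filter_band,
      threshold_ratio = threshold_ratio, max_peak_offset = max_peak_offset,
      full_scale = full_scale)
    pm[setdiff(names(pm), c("selcum_db", "aelcum_db"))]
  })
  append_cumulative(bind_rows(rows))
}

#' Locate the closest point of approach from pulse metrics
#'
#' The CPA shot is the retained pulse with the maximum zero-to-peak
#' pressure level (ties broken by the earliest shot).  When shot ranges
#' are supplied and nearly constant (a stationary session), the CPA is
#' reported as undefined.
#'
#' @param metrics per-pulse metrics tibble from [pulse_metrics()].
#' @param ranges optional per-shot ranges (m), aligned with `metrics`.
#' @param stationary_tolerance relative range spread below which the
#'   session counts as stationary.
#' @return A one-row tibble: `shot_id`, `time`, `p0pk_db`,
#'   `cpa_defined`.
#' @export
detect_cpa <- function(metrics, ranges = NULL, stationary_tolerance = 0.05) {
  ok <- !metrics$discarded & is.finite(metrics$p0pk_db)
  if (!any(ok))
    abort("detect_cpa: all pulses discarded", class = "pulsefish_domain_error")
  cpa_defined <- TRUE
  if (!is.null(ranges)) {
    spread <- (max(ranges) - min(ranges)) / max(min(ranges), 1e-9)
    if (spread < stationary_tolerance) cpa_defined <- FALSE
  }
  m <- metrics[ok, ]
  i <- which(m$p0pk_db == max(m$p0pk_db))[1]
  tibble(shot_id = m$shot_id[i], time = m$time[i], p0pk_db = m$p0pk_db[i],
         cpa_defined = cpa_defined)
}
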