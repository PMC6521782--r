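test_that("hydrophone and accelerometer calibrations follow their definitions", {
  # 1 V at -170 dB re 1V/uPa
  expect_equal(calibrate_pressure(1, -170, sample_rate = 4800)$samples,
               10^(170 / 20), tolerance = 1e-12)
  expect_equal(calibrate_pressure(0, -170, sample_rate = 4800)$samples, 0)
  # vector-sensor hydrophone: 1 mV at -180 dB
  expect_equal(calibrate_pressure(1e-3, -180, sample_rate = 4800)$samples,
               10^(180 / 20) * 1e-3, tolerance = 1e-9)
  expect_error(calibrate_pressure(1, NaN), class = "pulsefish_calibration_error")

  # 1 V at 1 V/g, g = 9.82
  expect_equal(unname(calibrate_acceleration(matrix(1, 1, 3),
                                             1)$samples[1, 1]), 9.82e6)
  expect_equal(calibrate_acceleration(0, 1), 0)
  expect_error(calibrate_acceleration(1, 0),
               class = "pulsefish_calibration_error")
  # sensor noise floor: 4 ug/sqrt(Hz) -> 39.28 um/s^2 -> ~32 dB re 1 um/s^2
  floor_um_s2 <- calibrate_acceleration(4e-6, 1)
  expect_equal(floor_um_s2, 39.28)
  expect_equal(round(amplitude_db(floor_um_s2)), 32)
})

test_that("amplitude-to-dB conversion is the 20 log10 rule", {
  expect_equal(amplitude_db(1, 1), 0)
  expect_equal(amplitude_db(1e6, 1), 120) # 1 Pa re 1 uPa
  expect_equal(amplitude_db(39.28, 1), 31.88, tolerance = 5e-3)
  expect_error(amplitude_db(0), class = "pulsefish_domain_error")
  expect_error(amplitude_db(-3), class = "pulsefish_domain_error")
})

test_that("band-pass filter passes the pulse band and rejects swell and DC", {
  fs <- 4800
  # 100 Hz tone preserved within 5%
  tone <- tone_segment(100, 1, fs)
  out <- bandpass(tone)
  steady <- out$samples[(fs / 2):fs]
  expect_equal(max(abs(steady)), 1, tolerance = 0.05)
  # 0.5 Hz swell attenuated > 20 dB (analytic third-order Butterworth
  # high-pass at a decade below the 5 Hz edge gives ~60 dB)
  t <- (0:(20 * fs - 1)) / fs
  swell <- acoustic_trace(sin(2 * pi * 0.5 * t), fs)
  sw_out <- bandpass(swell)
  tail_amp <- max(abs(sw_out$samples[(10 * fs):(20 * fs)]))
  expect_lt(20 * log10(tail_amp), -20)
  # constant offset removed
  dc <- acoustic_trace(rep(3, 2 * fs), fs)
  expect_lt(abs(mean(bandpass(dc)$samples[fs:(2 * fs)])), 1e-6)
  expect_error(bandpass(tone, 5, 3000), class = "pulsefish_config_error")
})

test_that("pulse windows align the peak near the segment start", {
  sc <- small_scene(seed = 6)
  ses <- simulate_session(sc, "stationary_shooting", seed = 6)
  p_f <- bandpass(ses$pressure)
  arrival <- ses$shots$fire_time[3] + ses$shots$range_m[3] / sc$sound_speed_ms
  w <- select_pulse_window(p_f, arrival)
  expect_false(w$discarded)
  expect_lte(w$peak_offset, 0.2)
  expect_equal(trace_length(w$exposure), sc$sample_rate)
  expect_equal(trace_length(w$background), sc$sample_rate)
  # background ends 1 s (the mid-point of the 1-2 s pre-pulse interval)
  # before the exposure segment
  expect_equal(w$exposure$start_time - trace_end_time(w$background), 1,
               tolerance = 1e-9)

  # silence: no pulse to find
  quiet <- acoustic_trace(rnorm(10 * sc$sample_rate), sc$sample_rate,
                          start_time = -5)
  w0 <- select_pulse_window(quiet, 0)
  expect_true(w0$discarded)
  expect_equal(w0$reason, "no pulse")

  # pulse exactly at the admissible segment start: zero offset
  fs <- sc$sample_rate
  x <- numeric(10 * fs)
  x[5 * fs + 1] <- 1
  spike <- acoustic_trace(x, fs, start_time = -5)
  w1 <- select_pulse_window(spike, 0, pre_roll = 0)
  expect_equal(w1$peak_offset, 0)
  expect_error(select_pulse_window(spike, 4.9),
               class = "pulsefish_extraction_error")
})

test_that("transient rejection flags burst-contaminated windows only", {
  fs <- 4800
  set.seed(13)
  x <- rnorm(10 * fs)
  x[5 * fs + 1] <- 400 # the pulse
  clean <- select_pulse_window(acoustic_trace(x, fs, start_time = -5), 0)
  expect_false(reject_transient(clean)$discarded)

  # spike 20x rms in the background segment (oracle: direct ratio)
  y <- x
  bg_idx <- round(3.5 * fs)
  y[bg_idx] <- 20 * sqrt(mean(x[(3 * fs):(4 * fs)]^2))
  w <- select_pulse_window(acoustic_trace(y, fs, start_time = -5), 0)
  wd <- reject_transient(w, threshold_ratio = 10)
  expect_true(wd$discarded)
  expect_equal(wd$reason, "background transient")
  # infinite threshold never discards on the background rule
  expect_false(reject_transient(w, threshold_ratio = Inf)$discarded)
})

test_that("zero-to-peak is the dB of the maximum absolute excursion", {
  fs <- 4800
  x <- numeric(fs)
  x[100] <- 1e5
  seg <- acoustic_trace(x, fs)
  expect_equal(zero_to_peak(seg), 100)
  expect_equal(zero_to_peak(acoustic_trace(-x, fs)), 100)
  expect_error(zero_to_peak(acoustic_trace(numeric(fs), fs)),
               class = "pulsefish_domain_error")
})

test_that("the ESD satisfies Parseval and resolves tones into 1 Hz bins", {
  fs <- 4800
  # unit-amplitude 1 s tone: energy 0.5 in its own bin
  tone <- tone_segment(100, 1, fs)
  esd <- exposure_spectral_density(tone)
  expect_equal(esd$density[esd$frequency == 100], 0.5, tolerance = 1e-9)
  expect_lt(sum(esd$density[esd$frequency != 100]), 1e-9)
  # white noise: bin sum = time-domain energy within 1e-6 relative
  set.seed(7)
  seg <- acoustic_trace(rnorm(fs), fs)
  esd2 <- exposure_spectral_density(seg)
  e_time <- sum(seg$samples^2) / fs
  expect_equal(sum(esd2$density), e_time, tolerance = 1e-6)
  # zeros map to zeros
  z <- exposure_spectral_density(acoustic_trace(numeric(fs), fs))
  expect_true(all(z$density == 0))
  expect_error(exposure_spectral_density(acoustic_trace(numeric(2 * fs), fs)),
               class = "pulsefish_contract_error")
})

test_that("SELsp integrates the 5-500 Hz band in dB re 1 uPa^2 s", {
  fs <- 4800
  # rms 1 uPa tone for 1 s: unit energy, 0 dB
  tone <- tone_segment(100, sqrt(2), fs)
  esd <- exposure_spectral_density(tone)
  expect_equal(sel_single_pulse(esd), 0, tolerance = 1e-9)
  # x10 amplitude: +20 dB
  esd10 <- exposure_spectral_density(tone_segment(100, 10 * sqrt(2), fs))
  expect_equal(sel_single_pulse(esd10), 20, tolerance = 1e-9)
  # band-limited pulse: SELsp = time-domain energy within 0.1 dB
  set.seed(5)
  sc <- small_scene()
  sig <- airgun_signature(sc)
  seg <- acoustic_trace(c(sig$samples,
                          numeric(fs - trace_length(sig))), fs)
  e_db <- 10 * log10(sum(seg$samples^2) / fs)
  expect_lt(abs(sel_single_pulse(exposure_spectral_density(seg)) - e_db),
            0.1)
  expect_error(sel_single_pulse(esd, 3000, 3100),
               class = "pulsefish_domain_error")
})

test_that("total-field AEL combines the axes bin-wise", {
  fs <- 4800
  t <- (0:(fs - 1)) / fs
  ax <- sin(2 * pi * 60 * t)
  zero <- numeric(fs)
  only_x <- acoustic_trace(cbind(ax, zero, zero), fs, kind = "acceleration3")
  esd <- exposure_spectral_density(only_x)
  total <- ael_single_pulse(esd)
  x_only <- 10 * log10(sum(esd$x[esd$frequency >= 5 & esd$frequency <= 500]))
  expect_equal(total, x_only, tolerance = 1e-12)
  # equal energy on three axes: +10 log10(3)
  eq3 <- acoustic_trace(cbind(ax, ax, ax), fs, kind = "acceleration3")
  expect_equal(ael_single_pulse(exposure_spectral_density(eq3)),
               x_only + 10 * log10(3), tolerance = 1e-9)
  # per-axis ESD interface with mismatched bins errors
  a <- tibble::tibble(frequency = 0:10, density = 1)
  b <- tibble::tibble(frequency = 0:11, density = 1)
  expect_error(ael_single_pulse(a, b, a), class = "pulsefish_contract_error")
})

test_that("AEL of a plane wave is invariant under rotation of the axes", {
  fs <- 4800
  set.seed(3)
  p <- acoustic_trace(rnorm(fs) * 50, fs)
  u <- c(0.3, -0.8, 0.52)
  u <- u / sqrt(sum(u^2))
  a <- plane_wave_acceleration(p, u, still_water)
  ael1 <- ael_single_pulse(exposure_spectral_density(a))
  rot <- rot_z(0.7)
  a_rot <- acoustic_trace(a$samples %*% t(rot), fs, kind = "acceleration3")
  ael2 <- ael_single_pulse(exposure_spectral_density(a_rot))
  expect_equal(ael1, ael2, tolerance = 0.01 / abs(ael1))
})

test_that("cumulative levels follow the energy-sum law", {
  one <- cumulative_level(152)
  expect_equal(one$cumulative_db, 152)
  # 60 identical pulses (oracle: closed form 152 + 10 log10 60)
  sixty <- cumulative_level(rep(152, 60))
  expect_equal(dplyr::last(sixty$cumulative_db), 152 + 10 * log10(60),
               tolerance = 1e-9)
  # arbitrary sequences: non-decreasing, final >= max single pulse
  set.seed(2)
  lv <- runif(40, 120, 160)
  cm <- cumulative_level(lv)
  expect_true(all(diff(cm$cumulative_db) >= 0))
  expect_gte(dplyr::last(cm$cumulative_db), max(lv))
  # discarded pulses are skipped
  cm2 <- cumulative_level(c(150, 170, 150), discarded = c(FALSE, TRUE, FALSE))
  expect_equal(dplyr::last(cm2$cumulative_db), 150 + 10 * log10(2),
               tolerance = 1e-9)
  expect_error(cumulative_level(numeric(0)), class = "pulsefish_domain_error")
})

test_that("rms level series reports 1 s interval levels", {
  fs <- 4800
  t <- (0:(10 * fs - 1)) / fs
  x <- sqrt(2) * sin(2 * pi * 100 * t) # rms 1
  s <- rms_level_series(acoustic_trace(x, fs))
  expect_equal(s$rms_db, rep(0, 10), tolerance = 1e-6)
  # x10 amplitude step: +20 dB
  x2 <- x
  x2[(5 * fs + 1):(10 * fs)] <- 10 * x2[(5 * fs + 1):(10 * fs)]
  s2 <- rms_level_series(acoustic_trace(x2, fs))
  expect_equal(s2$rms_db[10] - s2$rms_db[1], 20, tolerance = 1e-6)
  expect_error(rms_level_series(acoustic_trace(x[1:fs], fs), interval = 2),
               class = "pulsefish_contract_error")
})

test_that("amplitude scaling shifts every metric by exactly 20 log10 k", {
  sc <- small_scene(seed = 14)
  ses <- simulate_session(sc, "stationary_shooting", noise = FALSE, seed = 14)
  k <- 3.7
  scale_trace <- function(tr, k) {
    acoustic_trace(tr$samples * k, tr$sample_rate, tr$start_time, tr$kind)
  }
  m1 <- pulse_metrics(ses$pressure, ses$acceleration, ses$shots[1:3, ],
                      sound_speed = sc$sound_speed_ms)
  m2 <- pulse_metrics(scale_trace(ses$pressure, k),
                      scale_trace(ses$acceleration, k), ses$shots[1:3, ],
                      sound_speed = sc$sound_speed_ms)
  shift <- 20 * log10(k)
  for (col in c("p0pk_db", "selsp_db", "a0pk_db", "aelsp_db",
                "selcum_db", "aelcum_db")) {
    expect_equal(m2[[col]], m1[[col]] + shift, tolerance = 1e-9,
                 label = col)
  }
})

test_that("exposure metrics exceed background for well-separated pulses", {
  sc <- small_scene(seed = 15)
  ses <- simulate_session(sc, "stationary_shooting", seed = 15)
  m <- pulse_metrics(ses$pressure, ses$acceleration, ses$shots,
                     sound_speed = sc$sound_speed_ms)
  kept <- m[!m$discarded, ]
  # injected pulse-to-ambient separation here is far above 18 dB
  expect_true(all(kept$p0pk_db > kept$bg_p0pk_db))
  expect_true(all(kept$selsp_db > kept$bg_selsp_db))
  expect_true(all(kept$aelsp_db > kept$bg_aelsp_db))
})

test_that("clipped pulses are flagged and excluded from cumulative sums", {
  sc <- small_scene(seed = 16)
  ses <- simulate_session(sc, "stationary_shooting", noise = FALSE, seed = 16)
  full_scale <- max(abs(ses$pressure$samples)) * 0.9
  clipped <- pmin(pmax(ses$pressure$samples, -full_scale), full_scale)
  m <- pulse_metrics(acoustic_trace(clipped, sc$sample_rate,
                                    ses$pressure$start_time, "pressure"),
                     shots = ses$shots[1:3, ],
                     sound_speed = sc$sound_speed_ms,
                     full_scale = full_scale)
  expect_true(all(m$clipped))
  expect_true(all(is.na(m$selcum_db)))
})

test_that("CPA detection picks the maximum-level shot, earliest on ties", {
  m <- tibble::tibble(shot_id = 1:3, time = c(0, 10, 20),
                      p0pk_db = c(150, 160, 160),
                      discarded = FALSE)
  cpa <- detect_cpa(m)
  expect_equal(cpa$shot_id, 2)
  expect_error(detect_cpa(dplyr::mutate(m, discarded = TRUE)),
               class = "pulsefish_domain_error")
  single <- detect_cpa(m[1, ])
  expect_equal(single$shot_id, 1)
})
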