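test_that("airgun signature peak equals the configured zero-to-peak source level", {
  sc <- small_scene(source_level_p0pk = 220)
  sig <- airgun_signature(sc)
  expect_equal(max(abs(sig$samples)), 10^(220 / 20), tolerance = 1e-12)
  expect_lte(trace_length(sig) / sig$sample_rate, 1)
})

test_that("infinite damping collapses the signature to a single-sample impulse", {
  sc <- small_scene(damping = Inf)
  sig <- airgun_signature(sc)
  expect_equal(sig$samples[1], 10^(sc$source_level_p0pk / 20))
  expect_true(all(sig$samples[-1] == 0))
})

test_that("default signature concentrates >= 90% of its energy below 500 Hz", {
  sc <- small_scene()
  sig <- airgun_signature(sc)
  # oracle: direct DFT energy partition (Parseval)
  x <- sig$samples
  X <- fft(x)
  freqs <- (seq_along(x) - 1) * sig$sample_rate / length(x)
  pw <- Mod(X)^2
  low <- freqs <= 500 | freqs >= sig$sample_rate - 500 # conjugate half
  expect_gte(sum(pw[low]) / sum(pw), 0.90)
})

test_that("signature configuration errors are caught", {
  expect_error(scene_config(source_level_p0pk = -1),
               class = "pulsefish_config_error")
  expect_error(scene_config(bubble_period = NaN),
               class = "pulsefish_config_error")
  expect_error(scene_config(cpa_range = 7000),
               class = "pulsefish_config_error")
})

test_that("propagation applies spherical spreading and travel delay", {
  sc <- small_scene()
  sig <- airgun_signature(sc)
  # reference distance: identical waveform
  r1 <- propagate(sig, 1, still_water)
  expect_equal(r1$samples, sig$samples)
  # doubling range: -6.02 dB
  ra <- propagate(sig, 500, still_water)
  rb <- propagate(sig, 1000, still_water)
  expect_equal(20 * log10(max(abs(ra$samples)) / max(abs(rb$samples))),
               20 * log10(2), tolerance = 0.01 / 6)
  # onset delay = range / c (oracle: 100 / 1480 = 0.06757 by hand)
  rc <- propagate(sig, 100, still_water)
  expect_equal(rc$start_time - sig$start_time, 0.06757, tolerance = 1e-4)
  expect_error(propagate(sig, 0.5, still_water),
               class = "pulsefish_domain_error")
})

test_that("plane-wave acceleration matches the analytic tone relation", {
  fs <- 4800
  p0 <- 5
  f <- 100
  p <- tone_segment(f, p0, fs)
  a <- plane_wave_acceleration(p, c(1, 0, 0), still_water)
  expect_equal(max(abs(a$samples[, 1])),
               p0 * 2 * pi * f / (still_water$density * still_water$sound_speed),
               tolerance = 1e-3)
  expect_true(all(a$samples[, 2] == 0))
  expect_true(all(a$samples[, 3] == 0))
  expect_error(plane_wave_acceleration(p, c(0, 0, 0)),
               class = "pulsefish_domain_error")
  expect_error(plane_wave_acceleration(p, c(1, 1, 0)),
               class = "pulsefish_domain_error")
})

test_that("axis ESDs sum to the scalar-trace ESD for any direction", {
  fs <- 4800
  set.seed(11)
  p <- acoustic_trace(rnorm(fs) * 100, fs)
  u <- c(1, -2, 0.5)
  u <- u / sqrt(sum(u^2))
  a <- plane_wave_acceleration(p, u, still_water)
  esd3 <- exposure_spectral_density(a)
  scalar <- plane_wave_acceleration(p, c(1, 0, 0), still_water)
  esd1 <- exposure_spectral_density(scalar)
  nz <- esd1$x > max(esd1$x) * 1e-12
  expect_lt(max(abs(esd3$total[nz] - esd1$x[nz]) / esd1$x[nz]), 1e-6)
})

test_that("towed sessions peak at the CPA shot and stationary sessions stay level", {
  sc <- small_scene(seed = 3)
  ses <- simulate_session(sc, "towed_shooting", noise = FALSE)
  m <- pulse_metrics(ses$pressure, ses$acceleration, ses$shots,
                     sound_speed = sc$sound_speed_ms)
  cpa <- detect_cpa(m, ranges = ses$shots$range_m)
  expect_true(cpa$cpa_defined)
  expect_equal(cpa$shot_id, ses$shots$shot_id[which.min(ses$shots$range_m)])
  expect_equal(min(ses$shots$range_m), sc$cpa_range)

  st <- simulate_session(sc, "stationary_shooting", noise = TRUE, seed = 4)
  ms <- pulse_metrics(st$pressure, st$acceleration, st$shots,
                      sound_speed = sc$sound_speed_ms)
  kept <- ms$p0pk_db[!ms$discarded]
  expect_lt(max(kept) - min(kept), 1) # constant within ambient jitter
  expect_false(detect_cpa(ms, ranges = st$shots$range_m)$cpa_defined)
})

test_that("background sessions carry only ambient noise at the configured rms", {
  sc <- small_scene(seed = 9)
  bg <- simulate_session(sc, "background", duration = 120, seed = 9)
  expect_equal(nrow(bg$shots), 0)
  series <- rms_level_series(bg$pressure)
  expect_equal(mean(series$rms_db), sc$ambient_level_rms, tolerance = 0.5)
})

test_that("simulator outputs are bit-reproducible under a fixed seed", {
  sc <- small_scene(seed = 21)
  a <- simulate_session(sc, "stationary_shooting", seed = 21)
  b <- simulate_session(sc, "stationary_shooting", seed = 21)
  expect_identical(a$pressure$samples, b$pressure$samples)
  expect_identical(a$acceleration$samples, b$acceleration$samples)
  fr <- fish_response_config(seed = 5)
  s1 <- simulate_fish(sc, fr, single_shot(200), n_days = 1, n_fish = 2,
                      seed = 5)
  s2 <- simulate_fish(sc, fr, single_shot(200), n_days = 1, n_fish = 2,
                      seed = 5)
  expect_identical(s1$bio, s2$bio)
})

test_that("overlapping pulses are rejected as a configuration error", {
  sc <- small_scene(shot_interval = 0.5, pulse_duration = 0.6)
  expect_error(simulate_session(sc, "stationary_shooting"),
               class = "pulsefish_config_error")
})

test_that("fish heart rate responds to dose with the configured structure", {
  sc <- small_scene()
  shots <- simulate_shot_log(sc, "stationary_shooting", start_time = 30000,
                             day = 1)
  # null response: no dose dependence
  fr0 <- fish_response_config(bradycardia_gain = 0, seed = 2)
  s0 <- simulate_fish(sc, fr0, shots, n_days = 1, n_fish = 2,
                      n_reference_days = 0, seed = 2)
  dosed <- s0$bio$dose_db > 0
  expect_gt(sum(dosed), 0)
  expect_lt(abs(cor(s0$bio$heart_rate, s0$bio$dose_db)), 0.1)

  # large gain pins exposed heart rate at the logger floor
  fr_big <- fish_response_config(bradycardia_gain = 10, seed = 2)
  expect_warning(
    s_big <- simulate_fish(sc, fr_big, shots, n_days = 1, n_fish = 1,
                           n_reference_days = 0, seed = 2),
    "clipped")
  expect_true(all(s_big$bio$heart_rate[s_big$bio$dose_db > 20] == 10))
})

test_that("habituation halves the response each day as configured", {
  sc <- small_scene()
  shots <- dplyr::bind_rows(lapply(1:3, function(d)
    simulate_shot_log(sc, "stationary_shooting", start_time = 30000,
                      day = d)))
  fr <- fish_response_config(habituation_factor = 0.5, hr_noise_sd = 0.05,
                             activity_rate = 0, seed = 8)
  sim <- simulate_fish(sc, fr, shots, n_days = 3, n_fish = 4,
                       n_reference_days = 1, seed = 8)
  # per-day regression of heart rate on raw (unhabituated) dose
  slopes <- vapply(1:3, function(d) {
    b <- sim$bio[!is.na(sim$bio$exposure_day) & sim$bio$exposure_day == d, ]
    raw_dose <- b$dose_db / fr$habituation_factor^(d - 1)
    coef(lm(b$heart_rate ~ raw_dose))[[2]]
  }, numeric(1))
  # day-1 : day-3 response ratio ~ habituation^(-2) = 4
  expect_equal(slopes[1] / slopes[3], 4, tolerance = 0.15)
})

test_that("detection simulation honours geometry, drift and collisions", {
  array <- receiver_ring(8, 50, depths = c(3, 3))
  # tag at the cage centre, equal depth: identical arrivals
  track <- tibble::tibble(fish_id = "T1", time = c(0, 1000), x = 0, y = 0,
                          depth = 3)
  det <- simulate_detections(track, array, timing_noise_sd = 0, duty = 100,
                             seed = 1)
  one <- det[!det$is_sync & det$transmission_id == 1, ]
  expect_equal(length(unique(round(one$arrival_time, 12))), 1)

  # 10 ppm linear drift: sync deviation grows 36 ms per hour (oracle:
  # 3600 s x 1e-5)
  clock <- tibble::tibble(receiver_id = array$receiver_id, offset = 0,
                          drift = 1e-5)
  track_h <- tibble::tibble(fish_id = "T1", time = c(0, 3600), x = 5, y = 0,
                            depth = 3)
  det_h <- simulate_detections(track_h, array, clock = clock,
                               timing_noise_sd = 0, seed = 1)
  sync <- det_h[det_h$is_sync & det_h$receiver_id == "R1", ]
  dev <- sync$arrival_time - sync$emission_time
  span <- max(sync$emission_time) - min(sync$emission_time)
  expect_equal((max(dev) - min(dev)) / span * 3600, 0.036, tolerance = 1e-3)

  # same-channel transmissions within the collision window are all lost
  two <- tibble::tibble(fish_id = c("A", "B"),
                        time = c(0, 0), x = c(1, -1), y = 0, depth = 3)
  two <- dplyr::bind_rows(two, dplyr::mutate(two, time = 500))
  tags <- tibble::tibble(tag_id = c("A", "B"), frequency_khz = 69)
  det2 <- simulate_detections(two, array, tags = tags, duty = 500,
                              collision_window = 300, seed = 1)
  expect_false(any(c("A", "B") %in% det2$tag_id))

  # outside-cage track warns but still yields detections
  out_track <- tibble::tibble(fish_id = "T9", time = c(0, 200), x = 40,
                              y = 0, depth = 3)
  expect_warning(d9 <- simulate_detections(out_track, array, seed = 2),
                 "cage")
  expect_gt(nrow(d9), 0)
})
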