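# single-pulse AEL of the source signature at 1 m, via the package's own
# metric chain (plane-wave acceleration, 1 s window, 5-500 Hz ESD integral)
source_ael_db <- function(scene, band = c(5, 500)) {
  sig <- airgun_signature(scene)
  a <- plane_wave_acceleration(sig, c(1, 0, 0),
                               water = list(density = scene$water_density,
                                            sound_speed = scene$sound_speed_ms))
  fs <- scene$sample_rate
  pad <- round(fs) - trace_length(a)
  samples <- rbind(a$samples, matrix(0, pad, 3))
  ael_single_pulse(exposure_spectral_density(
    acoustic_trace(samples, fs, kind = "acceleration3")),
    f_lo = band[1], f_hi = band[2])
}

# in-band 1 s acceleration energy of the white ambient floor
ambient_ael_db <- function(scene, band = c(5, 500)) {
  r2 <- 10^(scene$ambient_accel_level_rms / 10)
  10 * log10(r2 * (band[2] - band[1] + 1) / (scene$sample_rate / 2))
}

#' Simulate biologger series and true tracks for a school of tagged fish
#'
#' Generates per-fish heart-rate/temperature biologger series on the
#' 2 min logger grid plus depth, body acceleration and a true horizontal
#' position track, over `n_reference_days` of undisturbed background
#' followed by `n_days` exposure days whose shot schedule is given by
#' `shot_logs`.  The response core is deterministic: during shooting the
#' heart rate drops by `bradycardia_gain` bpm per dB of
#' particle-acceleration exposure above ambient, attenuated by
#' `habituation_factor^(day - 1)`, and is floored at the logger's
#' recording floor; depth and distance from the cage centre shift by
#' `depth_shift_gain` per dB.  Around that core sit temperature
#' dependence, non-negative activity bursts and AR(1) measurement noise.
#'
#' @param scene a [scene_config()].
#' @param resp a [fish_response_config()].
#' @param shot_logs combined shot log for the exposure days (from
#'   [simulate_shot_log()] rows, needing `fire_time`, `range_m`, `day`).
#'   `fire_time` is interpreted relative to the start of each shot's
#'   exposure day.
#' @param n_days number of exposure days covered by `shot_logs`.
#' @param n_fish number of tagged fish.
#' @param n_reference_days background-only days preceding the exposures
#'   (the resting-baseline reference period).
#' @param species species label recycled across fish.
#' @param seed RNG seed; defaults to `resp$seed`.
#' @return A list: `bio` (tibble: `fish_id`, `species`, `time`, `day`,
#'   `exposure_day`, `heart_rate`, `quality`, `body_temperature`,
#'   `depth`, `body_acceleration`, `dist_origo`, `dose_db`), `track`
#'   (tibble: `fish_id`, `time`, `x`, `y`, `depth`), and the injected
#'   ground truth (`resting_hr`, `bradycardia_gain`, `ambient_ael_db`,
#'   `source_ael_db`).
#' @export
simulate_fish <- function(scene, resp, shot_logs, n_days,
                          n_fish = 8, n_reference_days = 2,
                          species = "cod", seed = NULL) {
  stopifnot(inherits(scene, "scene_config"),
            inherits(resp, "fish_response_config"))
  if (n_days < 1)
    abort("simulate_fish: n_days must be >= 1", class = "pulsefish_domain_error")
  if (nrow(shot_logs) > 0 && max(shot_logs$day) > n_days)
    abort("simulate_fish: shot_logs reference days beyond n_days",
          class = "pulsefish_domain_error")
  set.seed(seed %||% resp$seed)
  day_s <- 86400
  total_days <- n_reference_days + n_days
  dt <- resp$hr_sample_interval
  times <- seq(0, total_days * day_s - dt, by = dt)
  n_t <- length(times)
  cal_day <- floor(times / day_s) + 1
  exposure_day <- cal_day - n_reference_days
  exposure_day[exposure_day < 1] <- NA_integer_

  src_ael <- source_ael_db(scene)
  amb_ael <- ambient_ael_db(scene)
  # per-shot received AEL above ambient, on absolute time
  dose_at <- numeric(n_t)
  if (nrow(shot_logs) > 0) {
    shot_abs <- (shot_logs$day - 1 + n_reference_days) * day_s +
      shot_logs$fire_time
    shot_dose <- pmax(0, src_ael - 20 * log10(shot_logs$range_m) - amb_ael)
    for (i in seq_len(n_t)) {
      sel <- abs(shot_abs - times[i]) <= dt / 2
      if (any(sel)) dose_at[i] <- mean(shot_dose[sel])
    }
  }
  hab <- rep(1, n_t)
  hab[!is.na(exposure_day)] <-
    resp$habituation_factor^(exposure_day[!is.na(exposure_day)] - 1)

  t_ref <- 8
  r_cage <- scene$cage_diameter / 2

  one_fish <- function(f) {
    temp <- t_ref + 0.2 * sin(2 * pi * times / day_s) +
      stats::filter(rnorm(n_t, sd = 0.05), 0.9, method = "recursive",
                    init = 0)
    temp <- as.numeric(temp)
    activity <- rexp(n_t, rate = 1 / resp$activity_mean_bpm) *
      (runif(n_t) < resp$activity_rate)
    ar_noise <- as.numeric(stats::filter(rnorm(n_t, sd = resp$hr_noise_sd),
                                         resp$hr_noise_ar,
                                         method = "recursive", init = 0))
    hr <- resp$resting_hr + resp$hr_temp_slope * (temp - t_ref) + activity -
      resp$bradycardia_gain * dose_at * hab + ar_noise
    if (any(hr < 0))
      warn(sprintf("simulate_fish: fish %d heart rate clipped below zero before flooring", f))
    hr <- pmax(hr, resp$hr_floor)
    quality <- sample(c("Q0", "Q1", "Q2", "Q3"), n_t, replace = TRUE,
                      prob = c(0.7 * resp$qi_good_fraction,
                               0.3 * resp$qi_good_fraction,
                               0.7 * (1 - resp$qi_good_fraction),
                               0.3 * (1 - resp$qi_good_fraction)))
    depth_wander <- as.numeric(stats::filter(rnorm(n_t, sd = 0.6), 0.95,
                                             method = "recursive", init = 0))
    depth <- pmin(pmax(10 + depth_wander + resp$depth_shift_gain * dose_at *
                         hab, 0), scene$cage_depth)
    radius_wander <- as.numeric(stats::filter(rnorm(n_t, sd = 1.2), 0.9,
                                              method = "recursive", init = 0))
    radius <- pmin(pmax(0.45 * r_cage + radius_wander +
                          resp$depth_shift_gain * dose_at * hab, 0),
                   0.95 * r_cage)
    angle <- cumsum(rnorm(n_t, sd = 0.25)) + runif(1, 0, 2 * pi)
    accel <- pmin(pmax(0.25 + 0.04 * activity + rnorm(n_t, sd = 0.05), 0),
                  3.465)
    list(
      bio = tibble(
        fish_id = sprintf("F%02d", f), species = species,
        time = times, day = cal_day, exposure_day = exposure_day,
        heart_rate = hr, quality = quality, body_temperature = temp,
        depth = depth, body_acceleration = accel, dist_origo = radius,
        dose_db = dose_at * hab),
      track = tibble(
        fish_id = sprintf("F%02d", f), time = times,
        x = radius * cos(angle), y = radius * sin(angle), depth = depth)
    )
  }
  per_fish <- map(seq_len(n_fish), one_fish)
  list(bio = bind_rows(map(per_fish, "bio")),
       track = bind_rows(map(per_fish, "track")),
       resting_hr = resp$resting_hr,
       bradycardia_gain = resp$bradycardia_gain,
       ambient_ael_db = amb_ael, source_ael_db = src_ael)
}

#' Simulate tag detections at the receiver array
#'
#' Each tag transmits on its duty cycle from its true (interpolated)
#' position; every receiver records an arrival at
#' `emission + distance / c`, read through its own drifting clock
#' (`offset + drift * t`) plus Gaussian timing noise.  Transmissions of
#' tags sharing a frequency channel that fall within the collision
#' window of each other are lost on all receivers.  Fixed sync tags on a
#' known schedule are included for clock-model fitting.
#'
#' @param true_track tibble `fish_id` (tag id), `time`, `x`, `y`,
#'   `depth`.
#' @param array receiver tibble from [receiver_ring()].
#' @param tags tibble `tag_id`, `frequency_khz` (69/71); defaults to the
#'   tags present in `true_track` split across the two channels.
#' @param sound_speed_ms sound speed (m/s).
#' @param clock tibble `receiver_id`, `offset` (s), `drift` (s/s, e.g.
#'   1e-5 for 10 ppm); defaults to perfect clocks.
#' @param timing_noise_sd arrival-time noise sd (s).
#' @param duty transmission interval per tag (s).
#' @param collision_window same-channel transmissions closer than this
#'   are mutually lost (s).
#' @param sync_position length-3 sync-tag position (x, y, depth).
#' @param sync_interval sync-tag transmission interval (s).
#' @param cage_radius cage radius for the outside-cage warning (m).
#' @param seed RNG seed.
#' @return A tibble of detections: `tag_id`, `transmission_id`,
#'   `emission_time`, `receiver_id`, `arrival_time`, `frequency_khz`,
#'   `payload_depth`, `is_sync`.
#' @export
simulate_detections <- function(true_track, array, tags = NULL,
                                sound_speed_ms = 1480, clock = NULL,
                                timing_noise_sd = 0, duty = 80,
                                collision_window = 1,
                                sync_position = c(25, 0, 3),
                                sync_interval = 60, cage_radius = 25,
                                seed = 1L) {
  if (nrow(array) < 3)
    abort("simulate_detections: need >= 3 receivers",
          class = "pulsefish_domain_error")
  set.seed(seed)
  ids <- unique(true_track$fish_id)
  tags <- tags %||% tibble(
    tag_id = ids,
    frequency_khz = rep_len(c(69, 71), length(ids)))
  clock <- clock %||% tibble(receiver_id = array$receiver_id,
                             offset = 0, drift = 0)
  t0 <- min(true_track$time)
  t1 <- max(true_track$time)

  if (any(sqrt(true_track$x^2 + true_track$y^2) > cage_radius + 1e-6))
    warn("simulate_detections: track leaves the cage cylinder; detections still generated")

  # emission schedule: staggered duty cycles plus the sync tag
  emis <- map(seq_len(nrow(tags)), function(i) {
    tt <- filter(true_track, .data$fish_id == tags$tag_id[i])
    e_times <- seq(t0 + (i - 1) * duty / nrow(tags), t1, by = duty)
    tibble(tag_id = tags$tag_id[i],
           frequency_khz = tags$frequency_khz[i],
           emission_time = e_times,
           x = approx(tt$time, tt$x, e_times, rule = 2)$y,
           y = approx(tt$time, tt$y, e_times, rule = 2)$y,
           depth = approx(tt$time, tt$depth, e_times, rule = 2)$y,
           is_sync = FALSE)
  }) %>% bind_rows()
  sync <- map(unique(tags$frequency_khz), function(fk) {
    tibble(tag_id = paste0("SYNC", fk), frequency_khz = fk,
           emission_time = seq(t0 + 1, t1, by = sync_interval),
           x = sync_position[1], y = sync_position[2],
           depth = sync_position[3], is_sync = TRUE)
  }) %>% bind_rows()
  emis <- bind_rows(emis, sync) %>% arrange(.data$emission_time)

  # collision rule: same-channel emissions within the window are all lost
  emis <- emis %>%
    group_by(.data$frequency_khz) %>%
    arrange(.data$emission_time, .by_group = TRUE) %>%
    mutate(collided =
             (!is.na(lag(.data$emission_time)) &
                .data$emission_time - lag(.data$emission_time) < collision_window) |
             (!is.na(lead(.data$emission_time)) &
                lead(.data$emission_time) - .data$emission_time < collision_window)) %>%
    ungroup() %>%
    filter(!.data$collided) %>%
    group_by(.data$tag_id) %>%
    mutate(transmission_id = row_number()) %>%
    ungroup()

  det <- tidyr::crossing(emis, array %>%
                           rename(rx = "x", ry = "y", rdepth = "depth")) %>%
    left_join(clock, by = "receiver_id") %>%
    mutate(
      true_arrival = .data$emission_time +
        slant_range(.data$x, .data$y, .data$depth, .data$rx, .data$ry,
                    .data$rdepth) / sound_speed_ms,
      arrival_time = .data$true_arrival + .data$offset +
        .data$drift * .data$true_arrival +
        rnorm(dplyr::n(), sd = timing_noise_sd)) %>%
    select("tag_id", "transmission_id", "emission_time", "receiver_id",
           "arrival_time", "frequency_khz", payload_depth = "depth",
           "is_sync")
  det
}
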