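session_types <- c("towed_shooting", "towed_silent", "stationary_shooting",
                   "background")

#' Shot log and vessel track for one exposure session
#'
#' Lays out the firing schedule and source positions for one session in
#' the cage frame (origin at the cage centre).  Towed sessions run a
#' straight track past the cage at perpendicular distance `cpa_range`,
#' starting `transect_start_range` out; the shot grid is aligned so one
#' shot falls exactly at the CPA.  Stationary sessions fire from a fixed
#' point `stationary_range` away for `stationary_duration`.  Towed-silent
#' sessions carry the vessel track but no shots; background sessions have
#' neither.
#'
#' @param scene a [scene_config()].
#' @param session_type one of `"towed_shooting"`, `"towed_silent"`,
#'   `"stationary_shooting"`, `"background"`.
#' @param start_time session start (s, absolute).
#' @param day session day number (1-based); with
#'   `source_decay_db_per_day` set, later days fire at a lower source
#'   level.
#' @param post_cpa_range towed shooting continues until the range opens
#'   back to this value past the CPA (m).
#' @return A tibble (one row per shot): `shot_id`, `fire_time`, `x`,
#'   `y`, `z` (source position, m), `range_m` (horizontal range to cage
#'   centre), `session_type`, `day`, `source_level_db`; the vessel track
#'   is attached as attribute `"track"`.
#' @export
simulate_shot_log <- function(scene, session_type, start_time = 0, day = 1,
                              post_cpa_range = 500) {
  stopifnot(inherits(scene, "scene_config"))
  session_type <- match.arg(session_type, session_types)
  sl <- scene$source_level_p0pk - scene$source_decay_db_per_day * (day - 1)
  empty <- tibble(shot_id = integer(), fire_time = numeric(),
                  x = numeric(), y = numeric(), z = numeric(),
                  range_m = numeric(), session_type = character(),
                  day = integer(), source_level_db = numeric())

  if (session_type == "background") return(empty)

  if (session_type == "stationary_shooting") {
    n <- floor(scene$stationary_duration / scene$shot_interval)
    log <- tibble(
      shot_id = seq_len(n),
      fire_time = start_time + (seq_len(n) - 1) * scene$shot_interval,
      x = scene$cage_center[1] + scene$stationary_range,
      y = scene$cage_center[2],
      z = scene$airgun_depth,
      range_m = scene$stationary_range,
      session_type = session_type, day = as.integer(day),
      source_level_db = sl
    )
    return(log)
  }

  # towed track along x at perpendicular offset cpa_range, CPA at x = 0
  step <- scene$vessel_speed * scene$shot_interval
  s0 <- -sqrt(scene$transect_start_range^2 - scene$cpa_range^2)
  s0 <- -ceiling(-s0 / step) * step # align the grid so a shot sits at s = 0
  s_end <- sqrt(max(post_cpa_range^2 - scene$cpa_range^2, 0))
  s <- seq(s0, s_end, by = step)
  fire <- start_time + (s - s0) / scene$vessel_speed
  track <- tibble(time = fire,
                  x = scene$cage_center[1] + s,
                  y = scene$cage_center[2] + scene$cpa_range,
                  z = scene$airgun_depth)
  if (session_type == "towed_silent") {
    out <- empty
    attr(out, "track") <- track
    return(out)
  }
  out <- tibble(
    shot_id = seq_along(s), fire_time = fire,
    x = track$x, y = track$y, z = track$z,
    range_m = sqrt(s^2 + scene$cpa_range^2),
    session_type = session_type, day = as.integer(day),
    source_level_db = sl
  )
  attr(out, "track") <- track
  out
}

# spectrally tilted Gaussian ambient noise at an exact broadband rms level
ambient_noise <- function(n, fs, level_db_rms, shape_hz = 500) {
  x <- rnorm(n)
  if (!is.null(shape_hz) && shape_hz < fs / 2) {
    bf <- signal::butter(1, shape_hz / (fs / 2), type = "low")
    x <- as.numeric(signal::filter(bf, x))
  }
  x * 10^(level_db_rms / 20) / sqrt(mean(x^2))
}

# direction of propagation from a source position to the cage-mounted
# sensor (assumed at the cage centre, sensor_depth below the surface)
propagation_direction <- function(scene, src_xyz, sensor_depth = 5) {
  d <- c(scene$cage_center[1] - src_xyz[1],
         scene$cage_center[2] - src_xyz[2],
         sensor_depth - src_xyz[3])
  d / sqrt(sum(d^2))
}

# received pressure + acceleration snippet for one shot, in silence,
# covering [fire_time, fire_time + range/c + pulse_duration].  The
# plane-wave acceleration is differentiated once at the source (the
# derivative commutes with the delay and 1/r scaling), so long delayed
# traces never hit the FFT.
received_pulse <- function(scene, range_m, src_xyz, fire_time = 0,
                           signature = NULL, accel_scalar = NULL) {
  sig <- signature %||% airgun_signature(scene)
  water <- list(density = scene$water_density,
                sound_speed = scene$sound_speed_ms)
  if (is.null(accel_scalar))
    accel_scalar <- spectral_derivative(sig$samples, sig$sample_rate) /
      (water$density * water$sound_speed)
  fs <- sig$sample_rate
  r <- max(range_m, 1)
  delay_n <- round(r / water$sound_speed * fs)
  apply_path <- function(x) {
    out <- c(numeric(delay_n), x / r)
    if (!is.null(scene$surface_echo)) {
      echo_n <- round(scene$surface_echo$delay_s * fs)
      echo <- c(numeric(echo_n), out * scene$surface_echo$coefficient)
      out <- c(out, numeric(echo_n)) + echo
    }
    out
  }
  p <- apply_path(sig$samples)
  a_sc <- apply_path(accel_scalar)
  u <- propagation_direction(scene, src_xyz)
  list(pressure = acoustic_trace(p, fs, start_time = fire_time,
                                 kind = "pressure"),
       acceleration = acoustic_trace(cbind(a_sc * u[1], a_sc * u[2],
                                           a_sc * u[3]), fs,
                                     start_time = fire_time,
                                     kind = "acceleration3"),
       arrival_time = fire_time + range_m / water$sound_speed)
}

#' Synthesize the received traces of one exposure session
#'
#' Builds continuous pressure and 3-axis acceleration traces at the cage
#' sensor: each logged shot contributes a spherically spread,
#' travel-delayed airgun pulse (with its plane-wave particle-motion
#' counterpart), superposed on Gaussian ambient noise at the configured
#' rms level.  Memory scales with session duration times sample rate;
#' for full-length towed transects prefer the per-shot metric driver
#' [pulse_metrics_from_scene()].
#'
#' @param scene a [scene_config()].
#' @param session_type see [simulate_shot_log()].
#' @param start_time session start (s).
#' @param day session day (1-based).
#' @param duration trace duration (s); defaults to the span of the shot
#'   log plus lead-in/out, or 60 s for background sessions.
#' @param noise include ambient noise (`FALSE` gives pulses in silence).
#' @param seed RNG seed; defaults to `scene$seed`.
#' @param post_cpa_range passed to [simulate_shot_log()].
#' @return A list with `pressure` and `acceleration`
#'   ([acoustic_trace()]s) and `shots` (the shot log tibble).
#' @export
simulate_session <- function(scene, session_type, start_time = 0, day = 1,
                             duration = NULL, noise = TRUE,
                             seed = NULL, post_cpa_range = 500) {
  stopifnot(inherits(scene, "scene_config"))
  session_type <- match.arg(session_type, session_types)
  if (scene$pulse_duration > scene$shot_interval)
    abort("simulate_session: shot_interval shorter than pulse duration (overlapping pulses)",
          class = "pulsefish_config_error")
  set.seed(seed %||% scene$seed)
  fs <- scene$sample_rate
  shots <- simulate_shot_log(scene, session_type, start_time = start_time,
                             day = day, post_cpa_range = post_cpa_range)
  lead_in <- 5
  if (is.null(duration)) {
    duration <- if (nrow(shots) == 0) 60
    else max(shots$fire_time) - start_time +
      max(shots$range_m) / scene$sound_speed_ms + scene$pulse_duration +
      2 * lead_in
  }
  t0 <- start_time - lead_in
  n <- round(duration * fs) + round(lead_in * fs)
  p <- if (noise) ambient_noise(n, fs, scene$ambient_level_rms)
       else numeric(n)
  a <- if (noise) {
    matrix(rnorm(3 * n), ncol = 3) * 10^(scene$ambient_accel_level_rms / 20) / sqrt(3)
  } else matrix(0, n, 3)

  if (nrow(shots) > 0) {
    sig <- airgun_signature(scene_with_level(scene, shots$source_level_db[1]))
    for (i in seq_len(nrow(shots))) {
      rp <- received_pulse(scene, shots$range_m[i],
                           c(shots$x[i], shots$y[i], shots$z[i]),
                           fire_time = shots$fire_time[i], signature = sig)
      i0 <- round((shots$fire_time[i] - t0) * fs) + 1
      idx <- i0:(i0 + trace_length(rp$pressure) - 1)
      keep <- idx >= 1 & idx <= n
      p[idx[keep]] <- p[idx[keep]] + rp$pressure$samples[keep]
      a[idx[keep], ] <- a[idx[keep], ] + rp$acceleration$samples[keep, ]
    }
  }
  list(pressure = acoustic_trace(p, fs, start_time = t0, kind = "pressure"),
       acceleration = acoustic_trace(a, fs, start_time = t0,
                                     kind = "acceleration3"),
       shots = shots)
}

scene_with_level <- function(scene, level_db) {
  scene$source_level_p0pk <- level_db
  scene
}
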