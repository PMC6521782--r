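# small scenes keep the signal-processing tests fast while preserving
# the study geometry's structure
small_scene <- function(..., sample_rate = 4800, transect_start_range = 700,
                        stationary_duration = 60) {
  scene_config(sample_rate = sample_rate,
               transect_start_range = transect_start_range,
               stationary_duration = stationary_duration, ...)
}

still_water <- list(density = 1027, sound_speed = 1480)

# 1 s tone segment helper
tone_segment <- function(freq, amplitude = 1, fs = 4800, phase = 0) {
  t <- (0:(fs - 1)) / fs
  acoustic_trace(amplitude * sin(2 * pi * freq * t + phase), fs)
}

# one-shot log at a given range, in the cage frame
single_shot <- function(range_m, source_level_db = 220, fire_time = 0) {
  tibble::tibble(shot_id = 1L, fire_time = fire_time, x = range_m, y = 0,
                 z = 4, range_m = range_m, session_type = "towed_shooting",
                 day = 1L, source_level_db = source_level_db)
}

# rotation matrix about the z axis
rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}
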