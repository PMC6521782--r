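#' Scene configuration for synthetic airgun exposures
#'
#' Describes the study geometry and acoustics of a caged-fish airgun
#' exposure: a sea cage moored at the surface, an airgun towed along a
#' straight transect past the cage (or anchored at a fixed stand-off
#' range), firing on a regular schedule, over a background of ambient
#' noise.  The defaults reproduce the field layout the pipeline was
#' designed around: a 50 m diameter, 25 m deep cage, towing started
#' 6.7 km out at 8.3 km/h with one shot every 10 s, a closest point of
#' approach (CPA) of 100 m, and a 10 min stationary shooting session
#' 200 m away.
#'
#' @param cage_center numeric length-2, cage centre in the horizontal
#'   plane (m).  The cage centre is the coordinate origin ("origo") for
#'   all positioning downstream.
#' @param cage_diameter cage diameter (m).
#' @param cage_depth cage depth (m).
#' @param transect_start_range slant range from airgun to cage at the
#'   first towed shot (m).
#' @param vessel_speed towing speed (m/s); default is 8.3 km/h.
#' @param shot_interval time between shots (s).
#' @param cpa_range closest point of approach of the towed transect (m).
#' @param stationary_range airgun-to-cage range during stationary
#'   shooting (m).
#' @param stationary_duration duration of stationary shooting (s).
#' @param airgun_depth airgun tow depth (m).
#' @param source_level_p0pk zero-to-peak source level at 1 m
#'   (dB re 1 uPa).  The field study did not publish a source signature;
#'   the default 220 dB is an assumption chosen so received zero-to-peak
#'   levels across 100--6700 m span roughly 143--180 dB re 1 uPa.
#' @param primary_frequency centre frequency of the primary pulse (Hz).
#' @param bubble_period bubble-pulse oscillation period (s).
#' @param bubble_amplitude relative amplitude of successive bubble
#'   pulses (unitless, < 1).
#' @param damping exponential decay rate of each pulse (1/s).
#' @param pulse_duration synthesized source pulse duration (s, <= 1).
#' @param ambient_level_rms ambient noise rms level (dB re 1 uPa);
#'   default matches a 103 dB re 1 uPa fjord background.
#' @param ambient_accel_level_rms ambient particle-acceleration rms
#'   level (dB re 1 um/s^2) across the three axes combined; default is a
#'   broadband floor consistent with the sensor noise-floor densities.
#' @param water_density sea-water density (kg/m^3).
#' @param sound_speed_ms sound speed used by the simulator (m/s).
#' @param sample_rate sampling rate of synthesized traces (Hz).
#' @param surface_echo optional surface-reflection echo as
#'   `list(delay_s=, coefficient=)`, or `NULL` for none.
#' @param source_decay_db_per_day optional linear source-level decline
#'   per session day (dB/day), emulating falling airgun drive pressure.
#' @param seed integer seed used by simulator functions when they draw
#'   randomness.
#'
#' @return A `scene_config` list.
#' @examples
#' sc <- scene_config(sample_rate = 4800)
#' sc$cpa_range
#' @export
scene_config <- function(cage_center = c(0, 0),
                         cage_diameter = 50,
                         cage_depth = 25,
                         transect_start_range = 6700,
                         vessel_speed = 8.3 * 1000 / 3600,
                         shot_interval = 10,
                         cpa_range = 100,
                         stationary_range = 200,
                         stationary_duration = 600,
                         airgun_depth = 4,
                         source_level_p0pk = 220,
                         primary_frequency = 90,
                         bubble_period = 0.11,
                         bubble_amplitude = 0.45,
                         damping = 35,
                         pulse_duration = 0.6,
                         ambient_level_rms = 103,
                         ambient_accel_level_rms = 60,
                         water_density = 1027,
                         sound_speed_ms = 1480,
                         sample_rate = 14400,
                         surface_echo = NULL,
                         source_decay_db_per_day = 0,
                         seed = 1L) {
  cfg <- list(
    cage_center = as.numeric(cage_center),
    cage_diameter = cage_diameter, cage_depth = cage_depth,
    transect_start_range = transect_start_range,
    vessel_speed = vessel_speed, shot_interval = shot_interval,
    cpa_range = cpa_range, stationary_range = stationary_range,
    stationary_duration = stationary_duration, airgun_depth = airgun_depth,
    source_level_p0pk = source_level_p0pk,
    primary_frequency = primary_frequency,
    bubble_period = bubble_period, bubble_amplitude = bubble_amplitude,
    damping = damping, pulse_duration = pulse_duration,
    ambient_level_rms = ambient_level_rms,
    ambient_accel_level_rms = ambient_accel_level_rms,
    water_density = water_density, sound_speed_ms = sound_speed_ms,
    sample_rate = sample_rate, surface_echo = surface_echo,
    source_decay_db_per_day = source_decay_db_per_day,
    seed = as.integer(seed)
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  num <- cfg[setdiff(names(cfg), c("surface_echo", "seed", "cage_center"))]
  bad <- names(num)[!vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                              (is.finite(x) || identical(x, Inf)), logical(1))]
  # damping may be Inf (impulse limit); everything else must be finite
  bad <- setdiff(bad, if (identical(cfg$damping, Inf)) "damping" else character())
  if (length(bad))
    abort(paste0("scene_config: non-finite or non-scalar fields: ",
                 paste(bad, collapse = ", ")), class = "pulsefish_config_error")
  pos <- c("cage_diameter", "cage_depth", "transect_start_range",
           "vessel_speed", "shot_interval", "cpa_range", "stationary_range",
           "stationary_duration", "source_level_p0pk", "primary_frequency",
           "bubble_period", "damping", "pulse_duration", "sample_rate",
           "water_density", "sound_speed_ms")
  neg <- pos[vapply(pos, function(f) cfg[[f]] <= 0, logical(1))]
  if (length(neg))
    abort(paste0("scene_config: fields must be strictly positive: ",
                 paste(neg, collapse = ", ")), class = "pulsefish_config_error")
  if (cfg$cpa_range >= cfg$transect_start_range)
    abort("scene_config: cpa_range must be smaller than transect_start_range",
          class = "pulsefish_config_error")
  if (cfg$sample_rate < 2 * max(1000, cfg$primary_frequency))
    abort("scene_config: sample_rate must be at least twice the highest synthesized frequency",
          class = "pulsefish_config_error")
  if (cfg$pulse_duration > 1)
    abort("scene_config: pulse_duration must be <= 1 s",
          class = "pulsefish_config_error")
  invisible(cfg)
}

#' Fish response configuration for the biologger simulator
#'
#' Parameters of the deterministic dose-response core and its noise model
#' used by [simulate_fish()].  Heart rate follows
#' `resting + hr_temp_slope * (T - T_ref) + activity - gain * dose * habituation^(day-1)`,
#' floored at the logger's 10 bpm recording floor, where `dose` is the
#' particle-acceleration exposure level above ambient (dB) at the cage.
#'
#' @param resting_hr resting heart rate (bpm).
#' @param hr_temp_slope heart-rate sensitivity to body temperature
#'   (bpm per degC).
#' @param bradycardia_gain heart-rate drop per dB of AELsp above ambient
#'   (bpm/dB).  The default 0.5 bpm/dB drives a ~30 to ~12 bpm drop at a
#'   ~36 dB peak dose, the magnitude of bradycardia the loggers resolve.
#' @param habituation_factor multiplicative response decline per exposure
#'   day (unitless, 0 < f <= 1).
#' @param hr_floor lowest heart rate the logger can record (bpm).
#' @param hr_sample_interval biologger sampling interval (s).
#' @param hr_noise_sd innovation standard deviation of the AR(1)
#'   measurement noise (bpm).
#' @param hr_noise_ar AR(1) coefficient of the heart-rate noise.
#' @param activity_rate fraction of epochs with an activity-elevated
#'   heart rate (unitless).
#' @param activity_mean_bpm mean heart-rate elevation during activity
#'   bursts (bpm).
#' @param depth_shift_gain depth / distance-to-origo shift per dB of dose
#'   (m/dB).
#' @param qi_good_fraction fraction of heart-rate records labelled Q0/Q1.
#' @param seed integer seed.
#'
#' @return A `fish_response_config` list.
#' @export
fish_response_config <- function(resting_hr = 30,
                                 hr_temp_slope = 1.5,
                                 bradycardia_gain = 0.5,
                                 habituation_factor = 0.7,
                                 hr_floor = 10,
                                 hr_sample_interval = 120,
                                 hr_noise_sd = 0.3,
                                 hr_noise_ar = 0.4,
                                 activity_rate = 0.35,
                                 activity_mean_bpm = 4,
                                 depth_shift_gain = 0.08,
                                 qi_good_fraction = 0.89,
                                 seed = 1L) {
  cfg <- list(
    resting_hr = resting_hr, hr_temp_slope = hr_temp_slope,
    bradycardia_gain = bradycardia_gain,
    habituation_factor = habituation_factor, hr_floor = hr_floor,
    hr_sample_interval = hr_sample_interval, hr_noise_sd = hr_noise_sd,
    hr_noise_ar = hr_noise_ar, activity_rate = activity_rate,
    activity_mean_bpm = activity_mean_bpm,
    depth_shift_gain = depth_shift_gain,
    qi_good_fraction = qi_good_fraction, seed = as.integer(seed)
  )
  class(cfg) <- "fish_response_config"
  if (cfg$hr_floor <= 0)
    abort("fish_response_config: hr_floor must be positive",
          class = "pulsefish_config_error")
  if (cfg$habituation_factor <= 0 || cfg$habituation_factor > 1)
    abort("fish_response_config: habituation_factor must be in (0, 1]",
          class = "pulsefish_config_error")
  if (cfg$qi_good_fraction < 0 || cfg$qi_good_fraction > 1)
    abort("fish_response_config: qi_good_fraction must be in [0, 1]",
          class = "pulsefish_config_error")
  cfg
}
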