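default_run_config <- function() {
  list(
    scene = list(),
    fish = list(),
    n_days = 3,
    n_fish = 8,
    n_reference_days = 2,
    towed_start_s = 36000,     # towed shooting starts at 10:00 each day
    break_s = 6240,            # pause before stationary shooting (104 min)
    post_cpa_range = 500,
    band = c(5, 500),
    filter_band = c(5, 1000),
    positioning = list(enabled = TRUE, timing_noise_sd = 1e-4,
                       clock_drift = 1e-5, duty = 80, epoch = 80,
                       span_s = 10800),
    seed = 1
  )
}

#' Build the exposure schedule implied by a run configuration
#'
#' Absolute session intervals (towed shooting, towed silent return leg,
#' stationary shooting) for each exposure day, on the same clock as the
#' biologger series (reference days first).
#'
#' @param scene a [scene_config()].
#' @param cfg run configuration list (see [run_pipeline()]).
#' @return A tibble: `start`, `end`, `session_type`, `day`.
#' @export
build_schedule <- function(scene, cfg) {
  day_s <- 86400
  rows <- map(seq_len(cfg$n_days), function(d) {
    off <- (cfg$n_reference_days + d - 1) * day_s
    towed <- simulate_shot_log(scene, "towed_shooting",
                               start_time = cfg$towed_start_s, day = d,
                               post_cpa_range = cfg$post_cpa_range)
    towed_end <- max(towed$fire_time) + scene$shot_interval
    silent_dur <- (max(towed$range_m) - scene$stationary_range) /
      scene$vessel_speed
    stat_start <- towed_end + silent_dur + cfg$break_s
    tibble(
      start = off + c(cfg$towed_start_s, towed_end, stat_start),
      end = off + c(towed_end, towed_end + silent_dur,
                    stat_start + scene$stationary_duration),
      session_type = c("towed_shooting", "towed_silent",
                       "stationary_shooting"),
      day = d)
  })
  bind_rows(rows)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)), class = "pulsefish_stage_error")
  })
}

#' Run the full synthetic-scene analysis pipeline
#'
#' Executes simulate -> exposure metrics -> positioning -> response
#' analysis from one configuration and writes all stage outputs plus a
#' run manifest to `out_dir`.  Reruns with the same configuration and
#' seed are bit-identical.
#'
#' @param config a configuration list (or path to a YAML file with the
#'   same structure): fields `scene` and `fish` are argument lists for
#'   [scene_config()] / [fish_response_config()]; `n_days`, `n_fish`,
#'   `n_reference_days`, `towed_start_s`, `break_s`, `post_cpa_range`,
#'   `band`, `filter_band`, `positioning` (`enabled`,
#'   `timing_noise_sd`, `clock_drift`, `duty`, `epoch`, `span_s` — the
#'   telemetry span simulated, capped for tractability), `seed`.
#'   Omitted fields take the defaults of the field-study layout.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with `shots`, `metrics`, `schedule`,
#'   `bio`, `fixes`, `track_epochs`, `responses`, `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("pulsefish_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_run_config(), config)
  # YAML 1.1 reads bare exponents like 1e-4 as strings; coerce scalars
  num <- function(x) if (is.character(x) &&
                           !anyNA(suppressWarnings(as.numeric(x))))
    as.numeric(x) else x
  cfg[] <- lapply(cfg, function(x)
    if (is.list(x)) { x[] <- lapply(x, num); x } else num(x))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  day_s <- 86400

  scene <- with_stage("configure",
                      do.call(scene_config, c(cfg$scene,
                                              list(seed = cfg$seed))))
  fish <- with_stage("configure",
                     do.call(fish_response_config,
                             c(cfg$fish, list(seed = cfg$seed + 1))))

  shots <- with_stage("simulate", {
    bind_rows(map(seq_len(cfg$n_days), function(d) {
      towed <- simulate_shot_log(scene, "towed_shooting",
                                 start_time = cfg$towed_start_s, day = d,
                                 post_cpa_range = cfg$post_cpa_range)
      towed_end <- max(towed$fire_time) + scene$shot_interval
      silent_dur <- (max(towed$range_m) - scene$stationary_range) /
        scene$vessel_speed
      stat <- simulate_shot_log(scene, "stationary_shooting",
                                start_time = towed_end + silent_dur +
                                  cfg$break_s, day = d)
      stat$shot_id <- stat$shot_id + max(towed$shot_id)
      bind_rows(towed, stat)
    }))
  })
  schedule <- with_stage("simulate", build_schedule(scene, cfg))

  metrics <- with_stage("metrics", {
    m <- bind_rows(map(seq_len(cfg$n_days), function(d) {
      md <- pulse_metrics_from_scene(
        scene, filter(shots, .data$day == d), seed = cfg$seed + 10 + d,
        band = cfg$band, filter_band = cfg$filter_band)
      md$time <- md$time + (cfg$n_reference_days + d - 1) * day_s
      md$day <- d
      md
    }))
    append_cumulative(m[setdiff(names(m), c("selcum_db", "aelcum_db"))])
  })

  sim <- with_stage("simulate", {
    simulate_fish(scene, fish, shots, n_days = cfg$n_days,
                  n_fish = cfg$n_fish,
                  n_reference_days = cfg$n_reference_days,
                  seed = cfg$seed + 2)
  })

  fixes <- NULL
  track_epochs <- NULL
  if (isTRUE(cfg$positioning$enabled)) {
    pos <- cfg$positioning
    res <- with_stage("positioning", {
      array <- receiver_ring(8, scene$cage_diameter)
      span <- filter(sim$track, .data$time <= min(sim$track$time) +
                       pos$span_s)
      det <- simulate_detections(
        span, array, sound_speed_ms = scene$sound_speed_ms,
        clock = tibble(receiver_id = array$receiver_id, offset = 0,
                       drift = pos$clock_drift),
        timing_noise_sd = pos$timing_noise_sd, duty = pos$duty,
        seed = cfg$seed + 3)
      sync <- filter(det, .data$is_sync)
      clock <- fit_clock_drift(sync, array, sync_position = c(25, 0, 3),
                               sound_speed_ms = scene$sound_speed_ms)
      corrected <- correct_clock(filter(det, !.data$is_sync), clock)
      fx <- position_tags(corrected, array,
                          sound_speed_ms = scene$sound_speed_ms,
                          timing_noise_sd = max(pos$timing_noise_sd, 1e-6))
      list(fixes = fx, epochs = track_summarize(fx, epoch = pos$epoch))
    })
    fixes <- res$fixes
    track_epochs <- res$epochs
  }

  responses <- with_stage("responses", {
    response_table(sim$bio, schedule, metrics,
                   reference_window = c(0, cfg$n_reference_days * day_s))
  })

  manifest <- list(
    package = "pulsefish",
    version = as.character(utils::packageVersion("pulsefish")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    counts = list(shots = nrow(shots), pulses_retained =
                    sum(!metrics$discarded & !metrics$clipped),
                  pulses_discarded = sum(metrics$discarded),
                  bio_records = nrow(sim$bio),
                  fixes = if (is.null(fixes)) 0 else nrow(fixes),
                  fixes_flagged = if (is.null(fixes)) 0
                  else sum(fixes$flagged),
                  response_epochs = nrow(responses))
  )

  with_stage("write", {
    write_table(shots, file.path(out_dir, "shots.csv"))
    write_table(metrics, file.path(out_dir, "metrics.csv"))
    write_table(schedule, file.path(out_dir, "schedule.csv"))
    write_table(sim$bio, file.path(out_dir, "bio.csv"))
    if (!is.null(fixes)) {
      write_table(fixes, file.path(out_dir, "fixes.csv"))
      write_table(track_epochs, file.path(out_dir, "track_epochs.csv"))
    }
    write_table(as_tibble(responses), file.path(out_dir,
                                                "response_table.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  inform(sprintf(
    "pulsefish run: %d shots (%d retained), %d bio records, %d fixes, %d response epochs",
    manifest$counts$shots, manifest$counts$pulses_retained,
    manifest$counts$bio_records, manifest$counts$fixes,
    manifest$counts$response_epochs))

  invisible(list(shots = shots, metrics = metrics, schedule = schedule,
                 bio = sim$bio, fixes = fixes, track_epochs = track_epochs,
                 responses = responses, manifest = manifest,
                 out_dir = out_dir))
}
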