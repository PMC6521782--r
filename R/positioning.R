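#' Sea-water sound speed (Medwin's formula)
#'
#' Medwin's (1975) empirical formula:
#' `c = 1449.2 + 4.6 T - 0.055 T^2 + 0.00029 T^3
#'      + (1.34 - 0.010 T)(S - 35) + 0.016 z`
#' with temperature `T` in degC, salinity `S` in psu and depth `z` in m.
#' Monotonically increasing in temperature over the coastal study range,
#' which is what makes temperature correction of arrival times matter.
#'
#' @param temperature_C water temperature (degC), -2 to 35.
#' @param salinity_psu salinity (psu), 0 to 45.
#' @param depth_m depth (m), >= 0.
#' @return Sound speed (m/s).
#' @examples
#' sound_speed(8, 30, 2.5)
#' @export
sound_speed <- function(temperature_C, salinity_psu = 35, depth_m = 0) {
  if (any(temperature_C < -2 | temperature_C > 35))
    abort("sound_speed: temperature outside [-2, 35] degC",
          class = "pulsefish_domain_error")
  if (any(salinity_psu < 0 | salinity_psu > 45))
    abort("sound_speed: salinity outside [0, 45] psu",
          class = "pulsefish_domain_error")
  if (any(depth_m < 0))
    abort("sound_speed: depth must be non-negative",
          class = "pulsefish_domain_error")
  t <- temperature_C
  1449.2 + 4.6 * t - 0.055 * t^2 + 0.00029 * t^3 +
    (1.34 - 0.010 * t) * (salinity_psu - 35) + 0.016 * depth_m
}

#' Receiver array geometry helper
#'
#' Equally spaced receiver ring on the cage perimeter, alternating
#' between the two deployment depths — the stand-in geometry for eight
#' receivers on the outer ring of a 50 m cage at 2.5 and 4.5 m depth.
#'
#' @param n_receivers number of receivers.
#' @param cage_diameter cage diameter (m).
#' @param depths deployment depths cycled around the ring (m).
#' @return A tibble: `receiver_id`, `x`, `y`, `depth`.
#' @export
receiver_ring <- function(n_receivers = 8, cage_diameter = 50,
                          depths = c(2.5, 4.5)) {
  theta <- 2 * pi * (seq_len(n_receivers) - 1) / n_receivers
  tibble(receiver_id = paste0("R", seq_len(n_receivers)),
         x = cage_diameter / 2 * cos(theta),
         y = cage_diameter / 2 * sin(theta),
         depth = rep_len(depths, n_receivers))
}

slant_range <- function(x, y, depth, rx, ry, rdepth) {
  sqrt((x - rx)^2 + (y - ry)^2 + (depth - rdepth)^2)
}

#' Fit per-receiver clock models from sync-tag detections
#'
#' A fixed sync tag transmits on a known schedule; each receiver's
#' observed arrival times should equal emission time plus the (known)
#' geometric travel time.  The deviation is modelled per receiver as
#' `offset + drift * t` and fitted by ordinary least squares.  Applying
#' the model leaves residuals at the timing-noise level when the true
#' drift is linear.
#'
#' @param sync_detections tibble of sync-tag detections: `receiver_id`,
#'   `arrival_time` (raw receiver clock, s), `emission_time` (true
#'   schedule, s).
#' @param array receiver tibble (`receiver_id`, `x`, `y`, `depth`).
#' @param sync_position length-3 position of the sync tag (x, y, depth).
#' @param sound_speed_ms sound speed (m/s).
#' @return A `clock_model` object; use [tidy()] for per-receiver
#'   coefficients and [correct_clock()] to apply it.
#' @export
fit_clock_drift <- function(sync_detections, array, sync_position,
                            sound_speed_ms = 1480) {
  det <- left_join(sync_detections, array, by = "receiver_id")
  if (anyNA(det$x))
    abort("fit_clock_drift: detections reference unknown receivers",
          class = "pulsefish_contract_error")
  det <- det %>%
    mutate(travel = slant_range(sync_position[1], sync_position[2],
                                sync_position[3], .data$x, .data$y,
                                .data$depth) / sound_speed_ms,
           deviation = .data$arrival_time - .data$emission_time - .data$travel)
  by_rx <- split(det, det$receiver_id)
  fits <- tibble(
    receiver_id = names(by_rx),
    n_sync = vapply(by_rx, nrow, integer(1)),
    fit = unname(lapply(by_rx, function(g) {
      if (nrow(g) < 2) NULL
      else lm(deviation ~ emission_time, data = g)
    })))
  excluded <- fits$receiver_id[vapply(fits$fit, is.null, logical(1))]
  if (length(excluded))
    warn(paste0("fit_clock_drift: receivers with < 2 sync detections excluded: ",
                paste(excluded, collapse = ", ")))
  coefs <- fits %>%
    mutate(offset = map_dbl(.data$fit, ~ if (is.null(.x)) NA_real_
                            else coef(.x)[[1]]),
           drift = map_dbl(.data$fit, ~ if (is.null(.x)) NA_real_
                           else coef(.x)[[2]]),
           residual_rms = map_dbl(.data$fit, ~ if (is.null(.x)) NA_real_
                                  else sqrt(mean(resid(.x)^2)))) %>%
    select("receiver_id", "n_sync", "offset", "drift", "residual_rms")
  structure(list(coefficients = coefs, sound_speed_ms = sound_speed_ms),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("<clock_model>\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.clock_model <- function(x, ...) x$coefficients

#' @export
glance.clock_model <- function(x, ...) {
  tibble(n_receivers = nrow(x$coefficients),
         n_excluded = sum(is.na(x$coefficients$offset)),
         max_abs_drift = max(abs(x$coefficients$drift), na.rm = TRUE),
         mean_residual_rms = mean(x$coefficients$residual_rms, na.rm = TRUE))
}

#' Apply a clock model to raw detection times
#'
#' Subtracts each receiver's fitted `offset + drift * t` from its raw
#' arrival times.  Detections on receivers without an estimable clock
#' model are dropped with a warning.
#'
#' @param detections tibble with `receiver_id` and `arrival_time`.
#' @param clock a `clock_model` from [fit_clock_drift()].
#' @return The detections with a `corrected_time` column.
#' @export
correct_clock <- function(detections, clock) {
  stopifnot(inherits(clock, "clock_model"))
  out <- left_join(detections, clock$coefficients, by = "receiver_id") %>%
    mutate(corrected_time = .data$arrival_time - .data$offset -
             .data$drift * .data$arrival_time) %>%
    select(-"n_sync", -"offset", -"drift", -"residual_rms")
  if (anyNA(out$corrected_time)) {
    warn("correct_clock: dropping detections on receivers without a clock model")
    out <- filter(out, !is.na(.data$corrected_time))
  }
  out
}

#' TDOA position of one transmission
#'
#' Gauss-Newton least squares on the arrival-time residuals
#' `r_i = t_i - t0 - d_i(x, y) / c` over the unknowns (x, y, t0), with
#' the tag depth fixed from the pressure-sensor payload (the 2.5/4.5 m
#' receiver ring has no vertical aperture) and the cage centre as the
#' initial guess.  Equivalent to classical time-difference-of-arrival
#' multilateration, with the emission time profiled out.
#'
#' @param arrival_times corrected arrival times (s) at the receivers in
#'   `array_rows`.
#' @param array_rows receiver tibble rows (`x`, `y`, `depth`), >= 3.
#' @param sound_speed_ms sound speed (m/s).
#' @param tag_depth tag depth from the sensor payload (m).
#' @param max_iter,tol Gauss-Newton iteration cap and step tolerance.
#' @param residual_threshold fixes with residual rms above this (s) are
#'   flagged, not dropped.
#' @return A one-row tibble: `x`, `y`, `residual_rms`, `n_receivers`,
#'   `converged`, `flagged`.
#' @export
tdoa_position <- function(arrival_times, array_rows, sound_speed_ms = 1480,
                          tag_depth = 5, max_iter = 50, tol = 1e-12,
                          residual_threshold = Inf) {
  n <- length(arrival_times)
  if (n < 3 || nrow(array_rows) != n)
    abort("tdoa_position: need >= 3 receivers with matching arrival times",
          class = "pulsefish_domain_error")
  c_ms <- sound_speed_ms
  xy <- c(0, 0)
  d <- slant_range(xy[1], xy[2], tag_depth, array_rows$x, array_rows$y,
                   array_rows$depth)
  t0 <- mean(arrival_times - d / c_ms)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d <- slant_range(xy[1], xy[2], tag_depth, array_rows$x, array_rows$y,
                     array_rows$depth)
    r <- arrival_times - t0 - d / c_ms
    J <- cbind(-(xy[1] - array_rows$x) / (c_ms * d),
               -(xy[2] - array_rows$y) / (c_ms * d),
               rep(-1, n))
    step <- tryCatch(qr.solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    xy <- xy + step[1:2]
    t0 <- t0 + step[3]
    if (sqrt(sum(step[1:2]^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  d <- slant_range(xy[1], xy[2], tag_depth, array_rows$x, array_rows$y,
                   array_rows$depth)
  rms <- sqrt(mean((arrival_times - t0 - d / c_ms)^2))
  tibble(x = xy[1], y = xy[2], residual_rms = rms, n_receivers = n,
         converged = converged,
         flagged = !converged | rms > residual_threshold)
}

#' Position all transmissions in a detection table
#'
#' Groups corrected detections by tag and transmission, solves each
#' group with [tdoa_position()], and attaches the depth payload and the
#' distance to the cage-centre axis ("origo").
#'
#' @param detections tibble with `tag_id`, `transmission_id`,
#'   `receiver_id`, `corrected_time`, and optionally `payload_depth`.
#' @param array receiver tibble (`receiver_id`, `x`, `y`, `depth`).
#' @param sound_speed_ms sound speed (m/s).
#' @param timing_noise_sd expected arrival-time noise (s); the flagging
#'   threshold is 3x this value.
#' @param default_depth tag depth when no payload is present (m).
#' @return A tibble of position fixes: `tag_id`, `time` (mean corrected
#'   arrival), `x`, `y`, `depth`, `dist_origo`, `residual_rms`,
#'   `n_receivers`, `flagged`.
#' @export
position_tags <- function(detections, array, sound_speed_ms = 1480,
                          timing_noise_sd = 1e-4, default_depth = 5) {
  det <- left_join(detections, array, by = "receiver_id",
                   suffix = c("", "_rx"))
  groups <- det %>% group_by(.data$tag_id, .data$transmission_id)
  keys <- groups %>% dplyr::group_keys()
  fixes <- groups %>%
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 3) return(NULL)
      depth <- if ("payload_depth" %in% names(g) &&
                   any(!is.na(g$payload_depth)))
        median(g$payload_depth, na.rm = TRUE) else default_depth
      fix <- tdoa_position(g$corrected_time,
                           g[, c("x", "y", "depth")],
                           sound_speed_ms = sound_speed_ms,
                           tag_depth = depth,
                           residual_threshold = 3 * timing_noise_sd)
      fix$tag_id <- key$tag_id
      fix$transmission_id <- key$transmission_id
      fix$time <- mean(g$corrected_time)
      fix$depth <- depth
      fix
    }) %>%
    bind_rows()
  if (nrow(fixes) == 0)
    return(tibble(tag_id = character(), transmission_id = integer(),
                  time = numeric(), x = numeric(), y = numeric(),
                  depth = numeric(), dist_origo = numeric(),
                  residual_rms = numeric(), n_receivers = integer(),
                  flagged = logical()))
  fixes %>%
    mutate(dist_origo = sqrt(.data$x^2 + .data$y^2)) %>%
    select("tag_id", "transmission_id", "time", "x", "y", "depth",
           "dist_origo", "residual_rms", "n_receivers", "flagged")
}

#' Summarize position fixes to analysis epochs
#'
#' Per-epoch medians of distance-to-origo and depth on a regular epoch
#' grid (default the transmitter duty cycle, ~80 s); epochs with no fix
#' inside `max_gap` stay missing rather than being interpolated.
#'
#' @param fixes tibble from [position_tags()].
#' @param epoch epoch length (s).
#' @param max_gap maximum distance in time from an epoch centre to the
#'   nearest contributing fix (s); defaults to `epoch`.
#' @return A tibble: `tag_id`, `time` (epoch centre), `dist_origo`,
#'   `depth`, `n_fixes`.
#' @export
track_summarize <- function(fixes, epoch = 80, max_gap = epoch) {
  if (nrow(fixes) == 0)
    abort("track_summarize: no fixes", class = "pulsefish_domain_error")
  fixes %>%
    mutate(epoch_id = floor(.data$time / epoch)) %>%
    group_by(.data$tag_id, .data$epoch_id) %>%
    summarise(
      centre = (dplyr::first(.data$epoch_id) + 0.5) * epoch,
      gap = min(abs(.data$time - (dplyr::first(.data$epoch_id) + 0.5) * epoch)),
      dist_origo = median(.data$dist_origo),
      depth = median(.data$depth),
      n_fixes = dplyr::n(), .groups = "drop") %>%
    mutate(dist_origo = if_else(.data$gap <= max_gap, .data$dist_origo,
                                NA_real_),
           depth = if_else(.data$gap <= max_gap, .data$depth, NA_real_)) %>%
    select(tag_id = "tag_id", time = "centre", "dist_origo", "depth",
           "n_fixes")
}
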