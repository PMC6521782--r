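#' Filter biologger records by heart-rate quality index
#'
#' Keeps only records whose logger-assigned quality index is in `keep`
#' (Q0 = very good, Q1 = good by default) and reports the retention
#' fraction, the statistic quoted for a well-behaved deployment
#' (> 89 % Q0/Q1).
#'
#' @param bio biologger tibble with a `quality` column.
#' @param keep quality labels to retain.
#' @return The filtered tibble, with the retention fraction in attribute
#'   `"retention"` (also available via [qi_retention()]).
#' @export
filter_quality <- function(bio, keep = c("Q0", "Q1")) {
  if (!"quality" %in% names(bio))
    abort("filter_quality: no quality column", class = "pulsefish_contract_error")
  retained <- bio$quality %in% keep
  out <- bio[retained, , drop = FALSE]
  if (nrow(out) == 0)
    warn("filter_quality: no records retained; downstream baselines unestimable")
  attr(out, "retention") <- mean(retained)
  out
}

#' Retention fraction recorded by [filter_quality()]
#' @param bio a tibble returned by [filter_quality()].
#' @return The retained fraction of records.
#' @export
qi_retention <- function(bio) attr(bio, "retention")

#' Resting baseline: mean of the lowest decile
#'
#' The resting level of a variable over a reference period is the mean
#' of its lowest `fraction` (10 %) of values — a floor-seeking estimator
#' that ignores activity-elevated samples.
#'
#' @param values numeric values over the reference period.
#' @param fraction lower fraction to average.
#' @param min_n minimum number of values required.
#' @return The baseline value.
#' @examples
#' resting_baseline(60:69) # mean of the lowest value = 60
#' @export
resting_baseline <- function(values, fraction = 0.10, min_n = 10) {
  values <- values[!is.na(values)]
  if (length(values) < min_n)
    abort(sprintf("resting_baseline: need at least %d values", min_n),
          class = "pulsefish_domain_error")
  k <- ceiling(fraction * length(values))
  mean(sort(values)[seq_len(k)])
}

#' Deviation from a resting baseline
#'
#' @param values numeric series (missing values stay missing).
#' @param baseline resting baseline from [resting_baseline()].
#' @return `values - baseline`.
#' @export
change_from_resting <- function(values, baseline) {
  if (length(baseline) == 0 || !all(is.finite(baseline)))
    abort("change_from_resting: baseline not estimated",
          class = "pulsefish_domain_error")
  values - baseline
}

#' Correct a depth series for daily atmospheric pressure changes
#'
#' Tag pressure sensors read absolute pressure; daily barometric offsets
#' are converted hydrostatically (1 hPa ~ 1.02 cm of seawater) and
#' subtracted, clipping at the surface.
#'
#' @param depth depth series (m).
#' @param day day index per sample.
#' @param offsets_hpa tibble `day`, `offset_hpa` (deviation from the
#'   reference barometric pressure, hPa).
#' @param m_per_hpa hydrostatic conversion (m of seawater per hPa).
#' @return A tibble: `depth` (corrected, m), `clipped` (surface-clipped
#'   samples), `uncorrected` (days without an offset, left as-is).
#' @export
correct_depth_atmospheric <- function(depth, day, offsets_hpa,
                                      m_per_hpa = 0.0102) {
  off <- offsets_hpa$offset_hpa[match(day, offsets_hpa$day)]
  uncorrected <- is.na(off)
  if (any(uncorrected))
    warn("correct_depth_atmospheric: some days lack a barometric offset; left uncorrected")
  off[uncorrected] <- 0
  corrected <- depth - off * m_per_hpa
  clipped <- corrected < 0 & !is.na(corrected)
  corrected[clipped] <- 0
  tibble(depth = corrected, clipped = clipped, uncorrected = uncorrected)
}

#' Detrend a response variable on body temperature, per fish
#'
#' Fits an ordinary least-squares line of the variable on temperature
#' within each fish and returns the residuals, removing the shared
#' thermal dependence before dose-response analysis.  With constant
#' temperature the slope is unidentifiable and residuals fall back to
#' deviations from the mean, flagged.
#'
#' @param data tibble with the variable, temperature, and fish id.
#' @param var,temp,fish column names (strings).
#' @return The input with columns `<var>_resid` (residuals) and
#'   `detrend_flagged`; the per-fish fits are attached as attribute
#'   `"fits"` (a tibble usable with [tidy()] semantics: `fish`,
#'   `intercept`, `slope`, `r_squared`, `flagged`).
#' @export
detrend_temperature <- function(data, var, temp = "body_temperature",
                                fish = "fish_id") {
  stopifnot(all(c(var, temp, fish) %in% names(data)))
  resid_col <- paste0(var, "_resid")
  fits <- list()
  out <- data %>%
    group_by(.data[[fish]]) %>%
    dplyr::group_modify(function(g, key) {
      y <- g[[var]]
      x <- g[[temp]]
      ok <- is.finite(y) & is.finite(x)
      if (sum(ok) < 3)
        abort("detrend_temperature: need >= 3 paired points per fish",
              class = "pulsefish_domain_error")
      if (sd(x[ok]) == 0) {
        g[[resid_col]] <- y - mean(y[ok])
        g$detrend_flagged <- TRUE
        fits[[key[[1]][1]]] <<- tibble(intercept = mean(y[ok]),
                                       slope = NA_real_,
                                       r_squared = NA_real_, flagged = TRUE)
      } else {
        fit <- lm(y ~ x, data = tibble(y = y[ok], x = x[ok]))
        g[[resid_col]] <- NA_real_
        g[[resid_col]][ok] <- resid(fit)
        g$detrend_flagged <- FALSE
        fits[[key[[1]][1]]] <<- tibble(
          intercept = coef(fit)[[1]], slope = coef(fit)[[2]],
          r_squared = suppressWarnings(summary(fit)$r.squared),
          flagged = FALSE)
      }
      g
    }) %>%
    ungroup()
  attr(out, "fits") <- bind_rows(fits, .id = "fish")
  out
}

#' Label biologger epochs with exposure type and align sound metrics
#'
#' Tags each biologger epoch with the exposure session containing it
#' (towed shooting / towed silent / stationary shooting, anything else
#' is background), the session day, and the sound metrics of the
#' nearest-in-time retained pulse; epochs whose nearest pulse is farther
#' away than the shot interval get missing metrics.
#'
#' @param bio biologger tibble with a `time` column (epoch times, s).
#' @param schedule tibble of exposure intervals: `start`, `end`,
#'   `session_type`, `day`.
#' @param metrics per-pulse metrics tibble ([pulse_metrics()]) with
#'   `time`; discarded pulses are not matched.
#' @param shot_interval maximum epoch-to-pulse distance for a metric
#'   match (s).
#' @return `bio` with columns `session_type`, `exposure_day`, and the
#'   matched metric columns (`p0pk_db`, `selsp_db`, `a0pk_db`,
#'   `aelsp_db`, `selcum_db`, `aelcum_db`, `bg_selsp_db`,
#'   `bg_aelsp_db`).
#' @export
label_and_align <- function(bio, schedule, metrics = NULL,
                            shot_interval = 10) {
  if (nrow(schedule) > 0) {
    o <- order(schedule$start)
    s <- schedule[o, ]
    if (any(s$start[-1] < s$end[-nrow(s)]))
      abort("label_and_align: schedule intervals overlap",
            class = "pulsefish_contract_error")
  }
  lab <- rep("background", nrow(bio))
  sched_day <- rep(NA_integer_, nrow(bio))
  for (i in seq_len(nrow(schedule))) {
    inside <- bio$time >= schedule$start[i] & bio$time < schedule$end[i]
    lab[inside] <- schedule$session_type[i]
    sched_day[inside] <- schedule$day[i]
  }
  out <- bio
  out$session_type <- lab
  out$exposure_day <- sched_day
  metric_cols <- c("p0pk_db", "selsp_db", "a0pk_db", "aelsp_db",
                   "selcum_db", "aelcum_db", "bg_selsp_db", "bg_aelsp_db")
  if (!is.null(metrics)) {
    m <- filter(metrics, !.data$discarded)
    for (col in metric_cols) out[[col]] <- NA_real_
    if (nrow(m) > 0) {
      idx <- vapply(out$time, function(t) which.min(abs(m$time - t)),
                    integer(1))
      near <- abs(m$time[idx] - out$time) <= shot_interval
      for (col in intersect(metric_cols, names(m))) {
        v <- m[[col]][idx]
        v[!near] <- NA_real_
        out[[col]] <- v
      }
    }
  }
  out
}

#' Build the analysis-ready response table
#'
#' The hand-off artifact for mixed-model analysis: one row per fish and
#' biologger epoch carrying quality-filtered heart rate, changes from
#' per-fish resting baselines (heart rate, depth, body acceleration,
#' distance to origo), body temperature, temperature-detrended
#' residual heart rate, exposure labels and aligned sound metrics.
#'
#' @param bio biologger tibble (columns as produced by
#'   [simulate_fish()]'s `bio`, or the equivalent field import).
#' @param schedule exposure schedule tibble (`start`, `end`,
#'   `session_type`, `day`).
#' @param metrics per-pulse metrics tibble, optional.
#' @param reference_window length-2 time window (s) defining the
#'   resting-baseline reference period; defaults to everything before
#'   the first scheduled session.
#' @param keep_quality quality labels retained.
#' @param shot_interval metric matching tolerance (s).
#' @return A `response_table` tibble: identification, epoch labels,
#'   `heart_rate`, `hr_change`, `depth_change`, `accel_change`,
#'   `dist_change`, `body_temperature`, `hr_resid` (temperature
#'   detrended), and aligned sound metric columns.
#' @export
response_table <- function(bio, schedule, metrics = NULL,
                           reference_window = NULL,
                           keep_quality = c("Q0", "Q1"),
                           shot_interval = 10) {
  filtered <- filter_quality(bio, keep = keep_quality)
  retention <- qi_retention(filtered)
  ref <- reference_window %||%
    c(-Inf, if (nrow(schedule) > 0) min(schedule$start) else Inf)
  baselines <- filtered %>%
    filter(.data$time >= ref[1], .data$time < ref[2]) %>%
    group_by(.data$fish_id) %>%
    summarise(hr_rest = resting_baseline(.data$heart_rate),
              depth_rest = resting_baseline(.data$depth),
              accel_rest = resting_baseline(.data$body_acceleration),
              dist_rest = resting_baseline(.data$dist_origo),
              .groups = "drop")
  out <- filtered %>%
    left_join(baselines, by = "fish_id") %>%
    mutate(hr_change = change_from_resting(.data$heart_rate, .data$hr_rest),
           depth_change = change_from_resting(.data$depth, .data$depth_rest),
           accel_change = change_from_resting(.data$body_acceleration,
                                              .data$accel_rest),
           dist_change = change_from_resting(.data$dist_origo,
                                             .data$dist_rest))
  out <- detrend_temperature(out, "hr_change")
  fits <- attr(out, "fits")
  out <- out %>% rename(hr_resid = "hr_change_resid")
  out <- label_and_align(out, schedule, metrics,
                         shot_interval = shot_interval)
  attr(out, "retention") <- retention
  attr(out, "baselines") <- baselines
  attr(out, "detrend_fits") <- fits
  class(out) <- c("response_table", class(out))
  out
}

#' @export
glance.response_table <- function(x, ...) {
  tibble(n_epochs = nrow(x), n_fish = dplyr::n_distinct(x$fish_id),
         retention = attr(x, "retention"),
         n_shooting = sum(x$session_type %in%
                            c("towed_shooting", "stationary_shooting")))
}
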