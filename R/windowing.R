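#' Band-pass filter a trace
#'
#' Third-order Butterworth band-pass, 5--1000 Hz by default: wide enough
#' to keep the airgun pulse (energy mostly below 500 Hz) while rejecting
#' low-frequency swell and surface-wave motion.  Filtering is
#' single-pass (causal) by default so pulse and background windows share
#' the same constant group delay; a zero-phase forward-backward pass is
#' available as an option.
#'
#' @param trace an [acoustic_trace()].
#' @param low_hz,high_hz band edges (Hz), `0 < low < high < fs/2`.
#' @param order Butterworth order (3 = three poles per band edge).
#' @param zero_phase if `TRUE`, filter forward and backward
#'   (`signal::filtfilt`) instead of the causal single pass.
#' @return The filtered [acoustic_trace()].
#' @export
bandpass <- function(trace, low_hz = 5, high_hz = 1000, order = 3,
                     zero_phase = FALSE) {
  stopifnot(inherits(trace, "acoustic_trace"))
  fs <- trace$sample_rate
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    abort("bandpass: need 0 < low_hz < high_hz < sample_rate / 2",
          class = "pulsefish_config_error")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  ch <- trace_channels(trace)
  out <- apply(ch, 2, function(x) {
    if (zero_phase) signal::filtfilt(bf, x)
    else as.numeric(signal::filter(bf, x))
  })
  out <- matrix(out, ncol = ncol(ch))
  acoustic_trace(if (trace$kind == "pressure") out[, 1] else out,
                 fs, start_time = trace$start_time, kind = trace$kind)
}

#' Select the 1 s pulse and background analysis windows for a shot
#'
#' Finds the pulse peak near the expected arrival time and cuts a 1 s
#' exposure segment aligned so the peak sits at the beginning of the
#' segment, within `max_peak_offset` (200 ms) of its start, plus a 1 s
#' background segment ending `background_gap` seconds before the
#' exposure segment (inside the 1--2 s pre-pulse interval).  If no peak
#' stands clear of the surrounding samples the window is marked
#' discarded with reason `"no pulse"`.
#'
#' @param trace a band-passed [acoustic_trace()] covering at least
#'   `[shot_time - 3, shot_time + 1.5]` seconds.
#' @param shot_time expected pulse arrival time (s, absolute).
#' @param max_peak_offset latest admissible peak position within the
#'   exposure segment (s).
#' @param pre_roll nominal time between segment start and the peak (s).
#' @param background_gap gap between background segment end and
#'   exposure segment start (s); the background then occupies
#'   `[start - 1 - gap, start - gap]`.
#' @param detect_ratio minimum ratio of peak to search-region rms for a
#'   pulse to count as detected.
#' @param search_before,search_after extent of the peak search region
#'   around `shot_time` (s).
#' @return A `pulse_window` object: fields `exposure`, `background`
#'   (1 s [acoustic_trace()]s), `peak_offset` (s), `shot_time`,
#'   `discarded`, `reason`.
#' @export
select_pulse_window <- function(trace, shot_time, max_peak_offset = 0.2,
                                pre_roll = 0.05, background_gap = 1,
                                detect_ratio = 6,
                                search_before = 0.3, search_after = 1.3) {
  stopifnot(inherits(trace, "acoustic_trace"))
  fs <- trace$sample_rate
  if (trace$start_time > shot_time - 3 - 1e-9 ||
      trace_end_time(trace) < shot_time + 1.5 - 1e-9)
    abort("select_pulse_window: trace must cover [shot_time - 3, shot_time + 1.5] s",
          class = "pulsefish_extraction_error")

  region <- trace_slice(trace, shot_time - search_before,
                        shot_time + search_after)
  mag <- apply(abs(trace_channels(region)), 1, max)
  rms <- sqrt(mean(mag^2))
  i_pk <- which.max(mag)
  t_pk <- trace_times(region)[i_pk]

  discarded <- FALSE
  reason <- NA_character_
  if (rms == 0 || max(mag) < detect_ratio * rms) {
    discarded <- TRUE
    reason <- "no pulse"
    t_pk <- shot_time # nominal alignment for the degraded window
    seg_start <- t_pk
  } else {
    seg_start <- max(t_pk - pre_roll, trace$start_time)
  }
  # snap to the sample grid
  seg_start <- trace$start_time +
    round((seg_start - trace$start_time) * fs) / fs
  exposure <- trace_slice(trace, seg_start, seg_start + 1)
  background <- trace_slice(trace, seg_start - 1 - background_gap,
                            seg_start - background_gap)
  peak_offset <- t_pk - seg_start
  if (!discarded && peak_offset > max_peak_offset + 1e-9) {
    discarded <- TRUE
    reason <- "peak beyond max offset"
  }
  structure(
    list(exposure = exposure, background = background,
         peak_offset = peak_offset, shot_time = shot_time,
         discarded = discarded, reason = reason),
    class = "pulse_window"
  )
}

#' @export
print.pulse_window <- function(x, ...) {
  cat(sprintf("<pulse_window: shot at %.3f s, peak offset %.3f s%s>\n",
              x$shot_time, x$peak_offset,
              if (x$discarded) paste0(", DISCARDED (", x$reason, ")") else ""))
  invisible(x)
}

#' Flag windows contaminated by sharp transients
#'
#' Background segments recorded near the surface can contain bursts from
#' waves knocking the accelerometer; such windows must not contribute to
#' exposure/background comparisons.  A window is discarded when the
#' background segment's zero-to-peak exceeds `threshold_ratio` times its
#' rms (a burst far outside Gaussian expectation), or when a secondary
#' transient in the exposure segment, after the pulse itself has decayed,
#' reaches the pulse peak.
#'
#' @param window a `pulse_window` from [select_pulse_window()].
#' @param threshold_ratio background zero-to-peak / rms ratio above which
#'   the window is discarded; `Inf` disables the check.
#' @param pulse_span portion of the exposure segment attributed to the
#'   pulse itself (s); later samples are scanned for secondary
#'   transients.
#' @return The window, possibly with `discarded = TRUE` and a reason.
#' @export
reject_transient <- function(window, threshold_ratio = 10, pulse_span = 0.3) {
  stopifnot(inherits(window, "pulse_window"))
  if (window$discarded) return(window)
  bg <- apply(abs(trace_channels(window$background)), 1, max)
  if (any(bg > 0)) {
    if (max(bg) > threshold_ratio * sqrt(mean(bg^2))) {
      window$discarded <- TRUE
      window$reason <- "background transient"
      return(window)
    }
  }
  ex <- apply(abs(trace_channels(window$exposure)), 1, max)
  fs <- window$exposure$sample_rate
  late <- ex[seq.int(round(pulse_span * fs) + 1, length(ex))]
  if (max(late) >= max(ex)) {
    window$discarded <- TRUE
    window$reason <- "secondary transient"
  }
  window
}

# full-scale clipping: >= min_run consecutive samples at or above
# full_scale magnitude on any channel
is_clipped <- function(trace, full_scale, min_run = 3) {
  ch <- trace_channels(trace)
  any(apply(ch, 2, function(x) {
    at_fs <- abs(x) >= full_scale * (1 - 1e-9)
    if (!any(at_fs)) return(FALSE)
    r <- rle(at_fs)
    any(r$lengths[r$values] >= min_run)
  }))
}
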