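#' Calibrated acoustic trace
#'
#' A fixed-rate sample container in physical units: a single sound
#' pressure channel (uPa) or three particle-acceleration channels
#' (um/s^2, axes x/y in the horizontal plane and z vertical).
#'
#' @param samples numeric vector (pressure) or 3-column matrix
#'   (acceleration, columns x, y, z).
#' @param sample_rate sampling rate (Hz); must exceed 2000 so the
#'   5--1000 Hz analysis band is supported.
#' @param start_time absolute time of the first sample (s).
#' @param kind `"pressure"` or `"acceleration3"`.
#'
#' @return An `acoustic_trace` object.
#' @examples
#' tr <- acoustic_trace(sin(2 * pi * 100 * (0:4799) / 4800), 4800)
#' tr
#' @export
acoustic_trace <- function(samples, sample_rate, start_time = 0,
                           kind = c("pressure", "acceleration3")) {
  kind <- match.arg(kind)
  if (kind == "pressure") {
    samples <- as.numeric(samples)
    if (!all(is.finite(samples)))
      abort("acoustic_trace: samples must all be finite",
            class = "pulsefish_trace_error")
  } else {
    samples <- as.matrix(samples)
    if (ncol(samples) != 3)
      abort("acoustic_trace: acceleration3 requires exactly 3 channels",
            class = "pulsefish_trace_error")
    colnames(samples) <- c("x", "y", "z")
    if (!all(is.finite(samples)))
      abort("acoustic_trace: samples must all be finite",
            class = "pulsefish_trace_error")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 2000)
    abort("acoustic_trace: sample_rate must exceed 2000 Hz",
          class = "pulsefish_trace_error")
  structure(
    list(samples = samples, sample_rate = sample_rate,
         start_time = start_time, kind = kind),
    class = "acoustic_trace"
  )
}

#' @export
print.acoustic_trace <- function(x, ...) {
  n <- trace_length(x)
  cat(sprintf("<acoustic_trace: %s, %d samples @ %g Hz (%.3f s), start %.3f s>\n",
              x$kind, n, x$sample_rate, n / x$sample_rate, x$start_time))
  invisible(x)
}

trace_length <- function(trace) {
  if (is.matrix(trace$samples)) nrow(trace$samples) else length(trace$samples)
}

#' Time axis of a trace
#' @param trace an [acoustic_trace()].
#' @return numeric vector of absolute sample times (s).
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_len(trace_length(trace)) - 1) / trace$sample_rate
}

#' End time (exclusive) of a trace
#' @param trace an [acoustic_trace()].
#' @return absolute time just past the last sample (s).
#' @export
trace_end_time <- function(trace) {
  trace$start_time + trace_length(trace) / trace$sample_rate
}

# Extract [from, to) as sample indices; errors when outside the trace.
trace_slice <- function(trace, from, to) {
  i0 <- round((from - trace$start_time) * trace$sample_rate) + 1
  i1 <- round((to - trace$start_time) * trace$sample_rate)
  if (i0 < 1 || i1 > trace_length(trace) || i1 < i0)
    abort(sprintf("trace does not cover [%.3f, %.3f) s", from, to),
          class = "pulsefish_extraction_error")
  s <- if (is.matrix(trace$samples)) trace$samples[i0:i1, , drop = FALSE]
       else trace$samples[i0:i1]
  acoustic_trace(s, trace$sample_rate,
                 start_time = trace$start_time + (i0 - 1) / trace$sample_rate,
                 kind = trace$kind)
}

# channel matrix view (n x k), k = 1 or 3
trace_channels <- function(trace) {
  if (is.matrix(trace$samples)) trace$samples
  else matrix(trace$samples, ncol = 1)
}

#' Convert a trace to a tibble
#'
#' @param x an [acoustic_trace()].
#' @param ... unused.
#' @return A tibble with a `time` column and one column per channel
#'   (`pressure`, or `ax`/`ay`/`az`).
#' @export
as_tibble.acoustic_trace <- function(x, ...) {
  tm <- trace_times(x)
  if (x$kind == "pressure") {
    tibble(time = tm, pressure = x$samples)
  } else {
    tibble(time = tm, ax = x$samples[, 1], ay = x$samples[, 2],
           az = x$samples[, 3])
  }
}
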