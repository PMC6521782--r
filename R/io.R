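# ---- minimal RIFF/WAVE float32 I/O ---------------------------------------
# (format tag 3 = IEEE float, interleaved channels)

wav_write_float32 <- function(samples, sample_rate, path) {
  samples <- as.matrix(samples)
  n_ch <- ncol(samples)
  n <- nrow(samples)
  data_bytes <- 4L * n * n_ch
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")            # IEEE float
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 4 * n_ch), con, size = 4,
           endian = "little")
  writeBin(as.integer(4 * n_ch), con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(t(samples)), con, size = 4, endian = "little")
  invisible(path)
}

wav_read_float32 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF"))
    abort("wav_read: not a RIFF file", class = "pulsefish_io_error")
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE"))
    abort("wav_read: not a WAVE file", class = "pulsefish_io_error")
  sample_rate <- NULL; n_ch <- NULL; fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      n_ch <- readBin(con, integer(), size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (identical(id, "data")) {
      if (is.null(fmt) || fmt != 3L)
        abort("wav_read: only float32 WAV supported",
              class = "pulsefish_io_error")
      vals <- readBin(con, numeric(), n = sz / 4, size = 4,
                      endian = "little")
      samples <- matrix(vals, ncol = n_ch, byrow = TRUE)
    } else {
      readBin(con, raw(), n = sz)
    }
  }
  if (is.null(samples))
    abort("wav_read: no data chunk", class = "pulsefish_io_error")
  list(samples = samples, sample_rate = sample_rate)
}

# ---- calibrated audio with JSON sidecar ----------------------------------

#' Write scene audio as WAV plus a calibration sidecar
#'
#' Stores the pressure and 3-axis acceleration channels as one
#' four-channel float32 WAV in sensor volts (the calibrations are
#' inverted on write) and a JSON sidecar declaring channel names,
#' sensitivities and references, so the file can only be read back
#' through an explicit calibration.
#'
#' @param pressure pressure [acoustic_trace()] (uPa).
#' @param acceleration 3-axis acceleration [acoustic_trace()] (um/s^2).
#' @param path output WAV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param sensitivity_db hydrophone sensitivity recorded in the sidecar
#'   (dB re 1 V/uPa).
#' @param volts_per_g,g_value accelerometer calibration recorded in the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_audio <- function(pressure, acceleration, path,
                        sensitivity_db = -170, volts_per_g = 1,
                        g_value = 9.82) {
  stopifnot(pressure$sample_rate == acceleration$sample_rate,
            trace_length(pressure) == trace_length(acceleration))
  v_p <- pressure$samples * 10^(sensitivity_db / 20)
  v_a <- acceleration$samples / 1e6 / g_value * volts_per_g
  wav_write_float32(cbind(v_p, v_a), pressure$sample_rate, path)
  sidecar <- list(
    sample_rate = pressure$sample_rate,
    start_time = pressure$start_time,
    channels = list(
      list(name = "p", kind = "pressure", sensitivity_db = sensitivity_db,
           reference = "1 uPa"),
      list(name = "ax", kind = "acceleration", volts_per_g = volts_per_g,
           g_value = g_value, reference = "1 um/s^2"),
      list(name = "ay", kind = "acceleration", volts_per_g = volts_per_g,
           g_value = g_value, reference = "1 um/s^2"),
      list(name = "az", kind = "acceleration", volts_per_g = volts_per_g,
           g_value = g_value, reference = "1 um/s^2")))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read calibrated audio from WAV plus its sidecar
#'
#' Refuses to read without the calibration sidecar (no silent unit
#' guessing) and errors on a sample-rate mismatch between the WAV header
#' and the sidecar declaration.  Calibration goes through the same code
#' paths as [calibrate_pressure()] / [calibrate_acceleration()].
#'
#' @param path WAV path.
#' @param sidecar sidecar path, default `paste0(path, ".json")`.
#' @return A list with `pressure` and `acceleration`
#'   [acoustic_trace()]s.
#' @export
read_audio <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar))
    abort("read_audio: calibration sidecar missing; refusing to guess units",
          class = "pulsefish_io_error")
  meta <- jsonlite::read_json(sidecar)
  wav <- wav_read_float32(path)
  if (wav$sample_rate != meta$sample_rate)
    abort("read_audio: WAV sample rate does not match sidecar declaration",
          class = "pulsefish_io_error")
  kinds <- vapply(meta$channels, `[[`, character(1), "kind")
  ip <- which(kinds == "pressure")
  ia <- which(kinds == "acceleration")
  start <- meta$start_time %||% 0
  pressure <- calibrate_pressure(wav$samples[, ip],
                                 meta$channels[[ip]]$sensitivity_db,
                                 sample_rate = wav$sample_rate,
                                 start_time = start)
  acceleration <- NULL
  if (length(ia) == 3) {
    ch1 <- meta$channels[[ia[1]]]
    acceleration <- calibrate_acceleration(
      wav$samples[, ia, drop = FALSE], ch1$volts_per_g, ch1$g_value,
      sample_rate = wav$sample_rate, start_time = start)
  }
  list(pressure = pressure, acceleration = acceleration)
}

# ---- CSV contracts --------------------------------------------------------

#' Write / read the pipeline's CSV tables
#'
#' Plain comma-separated files with a mandatory header row and period
#' decimals.  Each reader enforces the expected columns so every file
#' the pipeline writes is re-readable by the package's own readers.
#'
#' @param x the tibble to write.
#' @param path file path.
#' @return `write_table()` returns `path` invisibly; readers return a
#'   tibble.
#' @name pulsefish_csv
NULL

#' @rdname pulsefish_csv
#' @export
write_table <- function(x, path) {
  readr::write_csv(dplyr::as_tibble(x), path)
  invisible(path)
}

read_checked <- function(path, required) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    abort(paste0("missing columns in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "pulsefish_io_error")
  x
}

#' @rdname pulsefish_csv
#' @param path file path.
#' @export
read_shot_log <- function(path) {
  read_checked(path, c("shot_id", "fire_time", "x", "y", "z", "range_m",
                       "session_type", "day"))
}

#' @rdname pulsefish_csv
#' @export
read_detections <- function(path) {
  read_checked(path, c("tag_id", "transmission_id", "receiver_id",
                       "arrival_time", "frequency_khz"))
}

#' @rdname pulsefish_csv
#' @export
read_bio <- function(path) {
  read_checked(path, c("fish_id", "time", "heart_rate", "quality",
                       "body_temperature"))
}

#' @rdname pulsefish_csv
#' @export
read_metrics <- function(path) {
  read_checked(path, c("shot_id", "time", "p0pk_db", "selsp_db",
                       "discarded"))
}

#' @rdname pulsefish_csv
#' @export
read_fixes <- function(path) {
  read_checked(path, c("tag_id", "time", "x", "y", "depth", "dist_origo",
                       "residual_rms", "n_receivers", "flagged"))
}

#' @rdname pulsefish_csv
#' @export
read_array <- function(path) {
  read_checked(path, c("receiver_id", "x", "y", "depth"))
}
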