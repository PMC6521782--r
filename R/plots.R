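#' Plot per-pulse exposure levels against time
#'
#' Received single-pulse levels with their background counterparts and
#' the running cumulative level — the standard transect picture: levels
#' rise to the CPA and fall away, cumulative levels staircase upward.
#'
#' @param metrics per-pulse metrics tibble from [pulse_metrics()].
#' @param which `"pressure"` (P0-pk / SELsp / SELcum) or
#'   `"acceleration"` (A0-pk / AELsp / AELcum).
#' @return A ggplot object.
#' @export
plot_pulse_metrics <- function(metrics, which = c("pressure",
                                                  "acceleration")) {
  which <- match.arg(which)
  cols <- if (which == "pressure")
    c(peak = "p0pk_db", single_pulse = "selsp_db",
      cumulative = "selcum_db", background = "bg_selsp_db")
  else c(peak = "a0pk_db", single_pulse = "aelsp_db",
         cumulative = "aelcum_db", background = "bg_aelsp_db")
  long <- metrics %>%
    filter(!.data$discarded) %>%
    select(time = "time", all_of(cols)) %>%
    tidyr::pivot_longer(-"time", names_to = "metric", values_to = "level_db")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$level_db,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)",
                  y = if (which == "pressure")
                    "level (dB re 1 µPa, µPa²s)"
                  else "level (dB re 1 µm/s², (µm/s²)²s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a band-limited energy series
#'
#' @param series tibble from [band_energy_series()].
#' @return A ggplot object.
#' @export
plot_band_energy <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(.data$time, .data$energy_db)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "5–500 Hz energy (dB)") +
    ggplot2::theme_minimal()
}

#' Plot position fixes inside the cage
#'
#' @param fixes tibble from [position_tags()].
#' @param cage_radius cage radius for the reference circle (m).
#' @return A ggplot object.
#' @export
plot_track <- function(fixes, cage_radius = 25) {
  theta <- seq(0, 2 * pi, length.out = 181)
  ring <- tibble(x = cage_radius * cos(theta), y = cage_radius * sin(theta))
  ggplot2::ggplot(fixes, ggplot2::aes(.data$x, .data$y,
                                      colour = .data$tag_id)) +
    ggplot2::geom_path(data = ring, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE, linetype = 2) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "tag") +
    ggplot2::theme_minimal()
}

#' Plot heart-rate change against exposure epochs
#'
#' @param responses a [response_table()].
#' @param fish optional subset of fish ids.
#' @return A ggplot object.
#' @export
plot_heart_rate <- function(responses, fish = NULL) {
  d <- responses
  if (!is.null(fish)) d <- filter(d, .data$fish_id %in% fish)
  ggplot2::ggplot(d, ggplot2::aes(.data$time / 86400, .data$hr_change,
                                  colour = .data$session_type)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::facet_wrap(~fish_id) +
    ggplot2::labs(x = "day", y = "heart rate change from resting (bpm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.acoustic_trace <- function(object, ...) {
  d <- as_tibble(object)
  long <- tidyr::pivot_longer(d, -"time", names_to = "channel",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)",
                  y = if (object$kind == "pressure") "pressure (µPa)"
                  else "acceleration (µm/s²)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.response_table <- function(object, ...) plot_heart_rate(object, ...)
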