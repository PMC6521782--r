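Package: pulsefish
Title: Airgun Sound-Exposure Metrics, Sea-Cage Telemetry Positioning and
    Fish Biologger Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying the exposure of caged
    fish to seismic airgun sound and their physiological and behavioural
    responses.  Computes ISO-18405-style per-pulse and cumulative sound
    pressure and particle-acceleration exposure metrics (P0-pk, SELsp,
    SELcum, A0-pk, AELsp, AELcum) from calibrated hydrophone and
    three-axis accelerometer traces; estimates horizontal tag positions in
    a sea cage by time-difference-of-arrival multilateration with sync-tag
    clock-drift correction and temperature-dependent sound speed; and
    transforms heart-rate, depth and acceleration biologger series into
    quality-filtered, baseline-referenced, temperature-detrended
    analysis-ready tables.  A synthetic-scene module generates airgun
    pulse trains, ambient noise, tag detections and fish biologger series
    with known ground truth so the whole chain is testable without field
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
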