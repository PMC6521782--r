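test_that("Medwin sound speed matches hand evaluation and is monotone in T", {
  # hand evaluation: 1449.2 + 4.6*8 - 0.055*64 + 0.00029*512
  #                  + (1.34 - 0.08)*(30 - 35) + 0.016*2.5 = 1476.36848
  expect_equal(sound_speed(8, 30, 2.5), 1476.36848, tolerance = 1e-8)
  # warmer water is faster over the study profile (8.0 -> 11.5 degC)
  expect_gt(sound_speed(11.5, 30, 15), sound_speed(8, 30, 15))
  # depth term is small in the upper 15 m
  expect_lt(abs(sound_speed(8, 30, 15) - sound_speed(8, 30, 2.5)), 0.3)
  expect_error(sound_speed(40), class = "pulsefish_domain_error")
  expect_error(sound_speed(8, 60), class = "pulsefish_domain_error")
})

test_that("clock models recover injected offset and drift", {
  array <- receiver_ring()
  track <- tibble::tibble(fish_id = "T1", time = c(0, 10800), x = 3, y = -2,
                          depth = 6)
  run_clock <- function(offset, drift, noise = 0) {
    det <- simulate_detections(track, array,
                               clock = tibble::tibble(
                                 receiver_id = array$receiver_id,
                                 offset = offset, drift = drift),
                               timing_noise_sd = noise, seed = 4)
    fit_clock_drift(det[det$is_sync, ], array, c(25, 0, 3))
  }
  # null case
  cm0 <- tidy(run_clock(0, 0))
  expect_true(all(abs(cm0$drift) < 1e-12))
  expect_true(all(abs(cm0$offset) < 1e-12))
  # constant offset only
  cm_off <- tidy(run_clock(0.25, 0))
  expect_equal(unname(cm_off$offset), rep(0.25, 8), tolerance = 1e-9)
  expect_true(all(abs(cm_off$drift) < 1e-12))
  # 10 ppm drift over 3 h, with realistic timing noise: within 2%
  cm_d <- tidy(run_clock(0, 1e-5, noise = 1e-4))
  expect_true(all(abs(cm_d$drift - 1e-5) / 1e-5 < 0.02))
})

test_that("receivers with too few sync detections are excluded with a warning", {
  array <- receiver_ring(4)
  det <- tibble::tibble(receiver_id = c("R1", "R1", "R2"),
                        arrival_time = c(10, 70, 10.01),
                        emission_time = c(10, 70, 10))
  expect_warning(cm <- fit_clock_drift(det, array, c(25, 0, 3)),
                 "excluded")
  td <- tidy(cm)
  expect_true(is.na(td$offset[td$receiver_id == "R2"]))
  expect_false(is.na(td$offset[td$receiver_id == "R1"]))
})

test_that("TDOA solving is exact at the symmetric centre and in silence", {
  array <- receiver_ring(8, 50, depths = c(3, 3))
  c_ms <- 1480
  # cage centre, same depth as the ring: perfect symmetry
  d <- sqrt(25^2 + 0^2)
  arrivals <- rep(100 + d / c_ms, 8)
  fix <- tdoa_position(arrivals, array, c_ms, tag_depth = 3)
  expect_lt(sqrt(fix$x^2 + fix$y^2), 1e-6)
  expect_error(tdoa_position(arrivals[1:2], array[1:2, ], c_ms),
               class = "pulsefish_domain_error")
})

test_that("noiseless synthetic transmissions are recovered to sub-mm", {
  set.seed(31)
  array <- receiver_ring()
  n <- 200
  r <- 24 * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  truth <- tibble::tibble(x = r * cos(th), y = r * sin(th),
                          depth = runif(n, 1, 24))
  errs <- vapply(seq_len(n), function(i) {
    d <- slant <- sqrt((truth$x[i] - array$x)^2 + (truth$y[i] - array$y)^2 +
                         (truth$depth[i] - array$depth)^2)
    fix <- tdoa_position(50 + d / 1480, array, 1480,
                         tag_depth = truth$depth[i])
    sqrt((fix$x - truth$x[i])^2 + (fix$y - truth$y[i])^2)
  }, numeric(1))
  expect_lt(max(errs), 1e-3)
})

test_that("position error scales with timing noise and stays under 0.5 m at 0.1 ms", {
  set.seed(32)
  array <- receiver_ring()
  one_rmse <- function(noise_sd, n) {
    r <- 20 * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    errs <- vapply(seq_len(n), function(i) {
      x <- r[i] * cos(th[i]); y <- r[i] * sin(th[i]); depth <- 8
      d <- sqrt((x - array$x)^2 + (y - array$y)^2 + (depth - array$depth)^2)
      fix <- tdoa_position(50 + d / 1480 + rnorm(8, sd = noise_sd), array,
                           1480, tag_depth = depth)
      (fix$x - x)^2 + (fix$y - y)^2
    }, numeric(1))
    sqrt(mean(errs))
  }
  rmse_01 <- one_rmse(1e-4, 500)
  expect_lt(rmse_01, 0.5)
  # near-linear growth with noise at small noise
  rmse_005 <- one_rmse(5e-5, 200)
  rmse_02 <- one_rmse(2e-4, 200)
  expect_equal(rmse_02 / rmse_005, 4, tolerance = 0.35)
})

test_that("distance to origo is invariant under joint rotation of ring and tags", {
  set.seed(33)
  array <- receiver_ring()
  x <- 7; y <- -11; depth <- 9
  d <- sqrt((x - array$x)^2 + (y - array$y)^2 + (depth - array$depth)^2)
  f1 <- tdoa_position(20 + d / 1480, array, 1480, tag_depth = depth)
  th <- 1.1
  arr2 <- array
  arr2$x <- array$x * cos(th) - array$y * sin(th)
  arr2$y <- array$x * sin(th) + array$y * cos(th)
  x2 <- x * cos(th) - y * sin(th)
  y2 <- x * sin(th) + y * cos(th)
  d2 <- sqrt((x2 - arr2$x)^2 + (y2 - arr2$y)^2 + (depth - arr2$depth)^2)
  f2 <- tdoa_position(20 + d2 / 1480, arr2, 1480, tag_depth = depth)
  expect_equal(sqrt(f1$x^2 + f1$y^2), sqrt(f2$x^2 + f2$y^2),
               tolerance = 1e-9)
})

test_that("the full detection-to-fix round trip recovers a moving track", {
  array <- receiver_ring()
  tt <- seq(0, 3000, by = 20)
  track <- tibble::tibble(fish_id = "T1", time = tt,
                          x = 12 * cos(tt / 500), y = 9 * sin(tt / 500),
                          depth = 8)
  det <- simulate_detections(track, array, timing_noise_sd = 0,
                             clock = tibble::tibble(
                               receiver_id = array$receiver_id,
                               offset = 0.02, drift = 5e-6),
                             duty = 60, seed = 12)
  clock <- fit_clock_drift(det[det$is_sync, ], array, c(25, 0, 3))
  fixes <- position_tags(correct_clock(det[!det$is_sync, ], clock), array,
                         timing_noise_sd = 1e-9)
  emis <- dplyr::distinct(det[!det$is_sync,
                              c("transmission_id", "emission_time")])
  j <- dplyr::inner_join(fixes, emis, by = "transmission_id")
  err <- sqrt((j$x - approx(tt, track$x, j$emission_time)$y)^2 +
                (j$y - approx(tt, track$y, j$emission_time)$y)^2)
  expect_lt(max(err), 1e-3)
  expect_true(all(fixes$n_receivers == 8))
})

test_that("track summaries give per-epoch medians and leave gaps missing", {
  fixes <- tibble::tibble(tag_id = "T1", transmission_id = 1:3,
                          time = c(10, 30, 500), x = c(3, 3, 0),
                          y = c(4, 4, 0),
                          depth = c(5, 5, 7),
                          dist_origo = c(5, 5, 0),
                          residual_rms = 0, n_receivers = 8, flagged = FALSE)
  ts <- track_summarize(fixes, epoch = 80)
  expect_equal(ts$dist_origo[ts$time == 40], 5) # 3-4-5 triangle
  # an epoch with no nearby fix is absent / missing, not interpolated
  expect_false(any(ts$time == 200))
  # all fixes at the centre: distance identically zero
  ctr <- dplyr::mutate(fixes, x = 0, y = 0, dist_origo = 0)
  expect_true(all(track_summarize(ctr, epoch = 80)$dist_origo == 0))
})
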