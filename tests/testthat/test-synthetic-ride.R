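test_that("ride configuration validates its invariants", {
  expect_error(ride_config(route_length = 150), "route_length")
  expect_error(ride_config(speed_mean = 2), "speed_mean")
  expect_error(ride_config(rri_sdnn_low = 60, rri_sdnn_high = 50))
  expect_error(ride_config(artifact_rates = c(ectopic = 1, spike = 0)))
  bad_profile <- matrix(2, 23, 3)
  expect_error(ride_config(stress_profile = bad_profile))
  cfg <- ride_config()
  expect_equal(cfg$n_segments, 23)
  expect_true(all(cfg$stress_profile >= 0 & cfg$stress_profile <= 1))
})

test_that("generated routes hit the requested length and are seed-deterministic", {
  for (len in c(2300, 2700)) {
    cfg <- ride_config(route_length = len, seed = 4)
    route <- generate_route(cfg)
    total <- arc_length(route$lat, route$lon)
    expect_lt(abs(total - len), 0.001 * len)
  }
  a <- generate_route(ride_config(seed = 9))
  b <- generate_route(ride_config(seed = 9))
  expect_identical(a, b)
  expect_false(identical(a, generate_route(ride_config(seed = 10))))
  # 2700 m at 100 m intervals supports 27 whole segments
  cfg27 <- ride_config(route_length = 2700, seed = 4)
  expect_equal(cfg27$n_segments, 27)
  expect_equal(nrow(chainage(generate_route(cfg27), 100)), 28)
})

test_that("GPS tracks follow the route at capped speed with requested gaps", {
  cfg <- ride_config(gps_noise_sd = 0, seed = 6)
  route <- generate_route(cfg)
  fixes <- generate_gps_track(route, cfg)
  # zero noise: every fix coincides with the noise-free path
  path <- attr(fixes, "path")
  expect_equal(fixes$lat, path$lat, tolerance = 1e-12)
  expect_true(all(fixes$speed <= 6 / 3.6 + 1e-9))
  # 1 Hz: consecutive timestamps differ by 1
  expect_true(all(diff(fixes$timestamp) == 1))

  # at the speed cap a 100 m segment takes ~60 s (>= 60 fixes)
  cfg_fast <- ride_config(speed_mean = 6 / 3.6, seed = 6)
  fx <- generate_gps_track(generate_route(cfg_fast), cfg_fast)
  pt <- attr(fx, "passage_times")
  durations <- diff(pt)
  expect_true(all(durations >= 60))
  expect_true(all(durations < 75))

  # a single 30 s gap produces exactly one missing run of 30 timestamps
  cfg_gap <- ride_config(seed = 6, gps_gap_spec = list(c(120, 30)))
  fg <- generate_gps_track(generate_route(cfg_gap), cfg_gap)
  missing <- setdiff(0:max(fg$timestamp), fg$timestamp)
  expect_equal(missing, 120:149)
})

test_that("environment streams couple to the stress profile", {
  profile <- matrix(c(0, 0.9, 0, 0.5, # vibration
                      0, 0.9, 0.5, 0, # encounters
                      0.9, 0, 0.5, 0), # width
                    nrow = 4)
  cfg <- ride_config(route_length = 400, stress_profile = profile, seed = 3)
  route <- generate_route(cfg)
  fixes <- generate_gps_track(route, cfg)
  env <- generate_environment(route, cfg, attr(fixes, "passage_times"))
  pt <- attr(fixes, "passage_times")

  # encounter intensity 0 -> no unique IDs first seen in those segments
  for (s in c(1, 4)) {
    seg <- data.frame(entry_time = pt[s], exit_time = pt[s + 1])
    expect_equal(count_encounters(env$encounters, seg), 0)
  }
  # sidewalk width narrows with intensity
  w1 <- min(env$widths$width_m[env$widths$chainage_start_m < 100])
  w2 <- min(env$widths$width_m[env$widths$chainage_start_m >= 100 &
                                 env$widths$chainage_start_m < 200])
  expect_gt(w2, w1)
  # env channels stay inside sensor ranges
  cleaned <- clean_env_stream(env$env)
  expect_equal(nrow(cleaned), nrow(env$env))
})

test_that("vibration RMS grows with intensity across seeds", {
  profile <- matrix(c(0.1, 0.9, 0, 0,
                      0.5, 0.5, 0.5, 0.5,
                      0.5, 0.5, 0.5, 0.5), nrow = 4)
  diffs <- vapply(1:60, function(seed) {
    cfg <- ride_config(route_length = 400, stress_profile = profile,
                       seed = seed)
    route <- generate_route(cfg)
    fixes <- generate_gps_track(route, cfg)
    env <- generate_environment(route, cfg, attr(fixes, "passage_times"))
    pt <- attr(fixes, "passage_times")
    rms_in <- function(s) {
      sel <- env$accel$timestamp >= pt[s] & env$accel$timestamp < pt[s + 1]
      sqrt(mean((env$accel$y[sel] - mean(env$accel$y[sel]))^2))
    }
    rms_in(2) - rms_in(1)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.95)
})

test_that("RRI generation is deterministic with stress-scaled variability", {
  cfg <- ride_config(seed = 14, artifact_rates = c(ectopic = 0, spike = 0))
  ride <- generate_ride(cfg, participants = 0, signals = "gps")
  a <- generate_rri(cfg, ride$truth, participant = 1)
  b <- generate_rri(cfg, ride$truth, participant = 1)
  expect_identical(a$series, b$series)
  expect_false(identical(a$series,
                         generate_rri(cfg, ride$truth, participant = 2)$series))
  expect_equal(a$injected_fraction, 0)

  # whole-ride SDNN in a single low-stress regime lands near the target
  cfg_flat <- ride_config(stress_profile = matrix(0, 23, 3), seed = 14,
                          artifact_rates = c(ectopic = 0, spike = 0))
  ride_flat <- suppressWarnings(
    generate_ride(cfg_flat, participants = 0, signals = "gps"))
  sdnns <- vapply(1:15, function(p) {
    rr <- generate_rri(cfg_flat, ride_flat$truth, participant = p)
    sd(rr$clean$rri_ms)
  }, numeric(1))
  expect_lt(abs(mean(sdnns) - 50) / 50, 0.2)
})

test_that("injected artifact fraction matches the requested rates", {
  cfg <- ride_config(seed = 8, artifact_rates = c(ectopic = 0.01, spike = 0.01))
  ride <- generate_ride(cfg, participants = 0, signals = "gps")
  fr <- vapply(1:10, function(p) {
    generate_rri(cfg, ride$truth, participant = p)$injected_fraction
  }, numeric(1))
  expect_true(all(abs(fr - 0.02) < 0.005))
})

test_that("ground truth is consistent with the scoring module", {
  cfg <- ride_config(seed = 19)
  ride <- generate_ride(cfg, participants = 0, signals = "gps")
  truth <- ride$truth
  recomputed <- compute_css(truth$levels)
  recomputed <- recomputed[order(recomputed$segment_id), ]
  expect_equal(recomputed$css, truth$css$css)
  expect_equal(recomputed$stress_level, truth$css$stress_level)
  expect_true(all(truth$css$css >= 3 & truth$css$css <= 9))
})

test_that("mean per-segment SDNN decreases with true stress level", {
  by_label <- matrix(NA_real_, 30, 3,
                     dimnames = list(NULL, c("Low", "Moderate", "High")))
  for (seed in 1:30) {
    cfg <- ride_config(seed = seed, artifact_rates = c(ectopic = 0, spike = 0))
    ride <- generate_ride(cfg, participants = 1, signals = c("gps", "rri"))
    pt <- ride$truth$passage_times
    segs <- data.frame(id = seq_len(cfg$n_segments),
                       entry_time = head(pt, -1), exit_time = tail(pt, -1))
    h <- compute_hrv_table(ride$rri[[1]]$clean, segs)
    lab <- ride$truth$css$stress_level[match(h$segment_id,
                                             ride$truth$css$segment_id)]
    agg <- tapply(h$sdnn, lab, mean)
    by_label[seed, names(agg)] <- agg
  }
  m <- colMeans(by_label, na.rm = TRUE)
  expect_gt(m["Low"], m["Moderate"])
  expect_gt(m["Moderate"], m["High"])
})

test_that("whole rides are reproducible from the seed", {
  a <- generate_ride(small_ride_config(seed = 33), participants = 1)
  b <- generate_ride(small_ride_config(seed = 33), participants = 1)
  expect_identical(a$gps$lat, b$gps$lat)
  expect_identical(a$accel$y, b$accel$y)
  expect_identical(a$encounters, b$encounters)
  expect_identical(a$rri[[1]]$series, b$rri[[1]]$series)
  expect_identical(a$truth$css, b$truth$css)
})
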