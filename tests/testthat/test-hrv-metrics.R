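rri_df <- function(rr) data.frame(beat_time = cumsum(rr) / 1000, rri_ms = rr)

test_that("ectopic bounds mask intervals outside 300-1300 ms, bounds survive", {
  out <- remove_ectopic(rri_df(c(800, 250, 900)))
  expect_equal(out$status, c("clean", "ectopic", "clean"))
  expect_equal(remove_ectopic(rri_df(c(800, 800)))$status, rep("clean", 2))
  scan <- remove_ectopic(rri_df(c(1400, 1300, 300, 299)))
  expect_equal(scan$status, c("ectopic", "clean", "clean", "ectopic"))
})

test_that("Hampel filter flags isolated outliers but not constant stretches", {
  const <- rri_df(rep(800, 30))
  expect_true(all(hampel_filter(const)$status == "clean"))
  spiked <- rri_df(c(rep(800, 10), 1200, rep(800, 10)))
  out <- hampel_filter(spiked)
  expect_equal(which(out$status == "hampel"), 11)
  # hand MAD check: window around the spike has median 800, MAD 0 ->
  # floor threshold 5 ms; |1200 - 800| = 400 exceeds it, neighbours do not
  expect_equal(sum(out$status == "hampel"), 1)
})

test_that("Hampel flags under 2% of an i.i.d. Gaussian series", {
  set.seed(31)
  rates <- replicate(30, {
    out <- hampel_filter(rri_df(rnorm(300, 900, 50)))
    mean(out$status == "hampel")
  })
  expect_lt(mean(rates), 0.02)
})

test_that("Hampel excludes ectopic beats from its window statistics", {
  # an ectopic run inside an otherwise constant series must not drag
  # the local median or inflate the MAD
  rr <- c(rep(800, 8), 200, 210, rep(800, 8))
  out <- hampel_filter(remove_ectopic(rri_df(rr)))
  expect_equal(sum(out$status == "ectopic"), 2)
  expect_equal(sum(out$status == "hampel"), 0)
})

test_that("quotient filter flags >10% jumps against the neighbour mean", {
  out <- quotient_filter(rri_df(c(800, 1000, 800)))
  expect_equal(out$status, c("clean", "quotient", "clean"))
  expect_true(all(quotient_filter(rri_df(c(800, 805, 800)))$status == "clean"))
  expect_true(all(quotient_filter(rri_df(rep(800, 10)))$status == "clean"))
  # endpoints are never tested
  out2 <- quotient_filter(rri_df(c(2000, 800, 810, 800, 2000)))
  expect_equal(out2$status[c(1, 5)], c("clean", "clean"))
})

test_that("interpolation fills masked beats and reports removal fractions", {
  clean <- rri_df(rep(800, 40))
  res <- interpolate_rri(clean)
  expect_equal(res$series$rri_ms, clean$rri_ms)
  expect_equal(res$report$total_removed, 0)
  expect_false(res$report$participant_excluded)
  # a smooth ramp with two masked beats is recovered exactly by the cubic
  rr <- seq(800, 995, by = 5)
  s <- rri_df(rr)
  s$status <- "clean"
  s$status[c(10, 25)] <- "hampel"
  res2 <- suppressWarnings(interpolate_rri(s))
  expect_equal(res2$series$rri_ms[c(10, 25)], rr[c(10, 25)], tolerance = 1e-9)
  expect_equal(res2$series$status[c(10, 25)], rep("interpolated", 2))
})

test_that("a 2.66% removal fraction keeps the participant; above 5% excludes", {
  rr <- rep(800, 10000)
  rr[seq_len(266)] <- 200 # ectopic
  res <- suppressWarnings(clean_rri(rri_df(rr)))
  expect_equal(res$report$fractions[["ectopic"]], 0.0266)
  expect_false(res$report$participant_excluded)
  rr2 <- rep(800, 1000)
  rr2[seq_len(60)] <- 200
  res2 <- suppressWarnings(clean_rri(rri_df(rr2)))
  expect_true(res2$report$participant_excluded)
})

test_that("time-domain indices match hand-computed values", {
  expect_null(compute_indices(rri_df(800)))
  const <- compute_indices(rri_df(rep(800, 50)))
  expect_equal(c(const$sdnn, const$rmssd, const$pnn50), c(0, 0, 0))
  two <- compute_indices(rri_df(c(800, 1000)))
  expect_equal(two$sdnn, 141.42, tolerance = 1e-4)
  jump <- compute_indices(rri_df(c(800, 851)))
  expect_equal(jump$rmssd, 51)
  expect_equal(jump$pnn50, 100)
  expect_equal(jump$mean_rr, 825.5)
})

test_that("indices agree with the brute-force oracle and are shift invariant", {
  set.seed(8)
  for (trial in 1:25) {
    rr <- runif(sample(20:200, 1), 500, 1200)
    got <- compute_indices(rri_df(rr))
    want <- oracle_hrv(rr)
    expect_equal(got$sdnn, want$sdnn, tolerance = 1e-9)
    expect_equal(got$rmssd, want$rmssd, tolerance = 1e-9)
    expect_equal(got$pnn50, want$pnn50, tolerance = 1e-9)
    shifted <- compute_indices(rri_df(rr + 100))
    expect_equal(c(shifted$sdnn, shifted$rmssd, shifted$pnn50),
                 c(got$sdnn, got$rmssd, got$pnn50), tolerance = 1e-9)
  }
})

test_that("segment windows select beats half-open by timestamp", {
  rr <- rep(1000, 10) # beats at 1, 2, ..., 10 s
  seg <- data.frame(id = 1L, entry_time = 2, exit_time = 5)
  rec <- compute_indices(rri_df(rr), seg)
  expect_equal(rec$n_beats, 3) # beats at 2, 3, 4
  expect_equal(rec$segment_id, 1L)
})

test_that("a clean synthetic series loses under 2% of beats to the filter chain", {
  losses <- vapply(1:10, function(seed) {
    cfg <- ride_config(seed = seed)
    ride <- generate_ride(cfg, participants = 0, signals = "gps")
    rr <- generate_rri(cfg, ride$truth, participant = 1)
    suppressWarnings(clean_rri(rr$clean))$report$total_removed
  }, numeric(1))
  expect_lt(mean(losses), 0.02)
  expect_true(all(losses < 0.04))
})

test_that("cleaning a spike-corrupted series recovers the clean oracle", {
  cfg <- ride_config(seed = 17,
                     artifact_rates = c(ectopic = 0, spike = 0.02))
  ride <- generate_ride(cfg, participants = 0, signals = "gps")
  rr <- generate_rri(cfg, ride$truth, participant = 1)
  res <- suppressWarnings(clean_rri(rr$series))
  rmse <- sqrt(mean((res$series$rri_ms - rr$clean$rri_ms)^2))
  expect_lt(rmse, 5)
})

test_that("z-scoring standardizes each participant's metrics across segments", {
  rec <- data.frame(participant = c(1, 1, 2, 2, 2),
                    segment_id = c(1, 2, 1, 2, 3),
                    sdnn = c(40, 60, 80, 100, 120),
                    rmssd = c(20, 30, 10, 20, 30),
                    pnn50 = c(5, 15, 0, 10, 20))
  z <- zscore_indices(rec)
  expect_equal(z$z_sdnn[1:2], c(-1, 1) / sqrt(2), tolerance = 1e-9)
  for (p in 1:2) {
    sel <- z$participant == p
    expect_equal(mean(z$z_sdnn[sel]), 0, tolerance = 1e-12)
    expect_equal(sd(z$z_sdnn[sel]), 1, tolerance = 1e-12)
  }
  # idempotence: z-scoring standardized values changes nothing
  rec2 <- rec
  rec2[, c("sdnn", "rmssd", "pnn50")] <- z[, c("z_sdnn", "z_rmssd", "z_pnn50")]
  z2 <- zscore_indices(rec2)
  expect_equal(z2$z_sdnn, z$z_sdnn, tolerance = 1e-12)
  # zero variance -> z = 0 with warning
  flat <- data.frame(participant = 1, segment_id = 1:3, sdnn = 5,
                     rmssd = c(1, 2, 3), pnn50 = c(1, 2, 3))
  expect_warning(zf <- zscore_indices(flat), "zero variance")
  expect_equal(zf$z_sdnn, c(0, 0, 0))
})
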