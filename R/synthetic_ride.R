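# Seeded synthetic rides with known ground-truth stress structure. Every
# sensor stream the pipeline ingests can be generated here: a loop route,
# 1 Hz GPS with noise and gaps, 100 Hz tri-axial acceleration with a
# gravity/mounting offset and road-surface-dependent vibration, 0.5 Hz
# environmental channels, a unique-person encounter stream, a sidewalk-width
# map, and beat-timestamped RRI series with injected artifacts and
# stress-coupled HRV suppression. All randomness flows from a single seed
# through fixed per-signal substreams.

# per-signal RNG substreams derived from the single config seed
substream <- function(config, k) set.seed((config$seed * 31L + k) %% 2147483647L)

#' Configuration for a synthetic ride
#'
#' Defaults describe the study conditions the package is validated under: a
#' 2,350 m urban loop divided into 100 m segments (23 whole segments), travel
#' near 1.25 m/s under the 6 km/h cap with a 30 s stationary lead-in, RRI
#' around a 900 ms baseline whose within-segment SDNN is 50 ms when relaxed
#' and 30 ms under full high-stress suppression (a 40% reduction), and 2%
#' injected RRI artifacts (1% ectopic, 1% spikes).
#'
#' @param route_length Route length in metres.
#' @param segment_interval Segment length in metres (default 100).
#' @param speed_mean Mean travel speed, m/s; must respect the 1.667 m/s
#'   (6 km/h) cap.
#' @param gps_noise_sd Isotropic GPS position noise, metres.
#' @param gps_gap_spec List of `c(start_s, duration_s)` GPS dropouts.
#' @param stress_profile n_segments x 3 matrix of true factor intensities in
#'   \[0, 1\] (columns vibration, encounters, width); NULL draws a
#'   well-separated profile from \{0.1, 0.5, 0.9\}.
#' @param stationary_s Stationary lead-in before the ride starts, seconds.
#' @param rri_baseline_mean Mean RR interval, ms.
#' @param rri_sdnn_low SDNN under full high-stress suppression, ms.
#' @param rri_sdnn_high Relaxed (low-stress) SDNN, ms.
#' @param artifact_rates Named fractions `c(ectopic = , spike = )` in \[0, 1).
#' @param vib_floor,vib_slope Vertical vibration noise sigma model,
#'   `sigma = vib_floor + vib_slope * intensity` (m/s^2).
#' @param encounter_scale Expected unique persons per segment at intensity 1.
#' @param seed Integer master seed.
#' @return A `ride_config` list.
#' @export
ride_config <- function(route_length = 2350, segment_interval = 100,
                        speed_mean = 1.25, gps_noise_sd = 2,
                        gps_gap_spec = list(), stress_profile = NULL,
                        stationary_s = 30, rri_baseline_mean = 900,
                        rri_sdnn_low = 30, rri_sdnn_high = 50,
                        artifact_rates = c(ectopic = 0.01, spike = 0.01),
                        vib_floor = 0.05, vib_slope = 0.8,
                        encounter_scale = 30, seed = 1) {
  stopifnot(route_length > 0, segment_interval > 0,
            route_length >= 2 * segment_interval,
            speed_mean > 0, speed_mean <= 6 / 3.6,
            gps_noise_sd >= 0,
            rri_sdnn_low < rri_sdnn_high, rri_sdnn_low > 0,
            all(artifact_rates >= 0), all(artifact_rates < 1),
            seed == as.integer(seed), abs(seed) < 2^26)
  n_segments <- floor(route_length / segment_interval)
  if (is.null(stress_profile)) {
    # well-separated intensities, stratified so each factor's level counts
    # line up with the 1/3 and 2/3 tertile cut positions
    substream(list(seed = seed), 0L)
    k1 <- floor(1 + (n_segments - 1) / 3)
    k2 <- floor(1 + 2 * (n_segments - 1) / 3)
    base_levels <- rep(1:3, c(k1, k2 - k1, n_segments - k2))
    stress_profile <- vapply(1:3, function(j) {
      c(0.1, 0.5, 0.9)[sample(base_levels)]
    }, numeric(n_segments))
    colnames(stress_profile) <- c("vibration", "encounters", "width")
  }
  stress_profile <- as.matrix(stress_profile)
  stopifnot(nrow(stress_profile) == n_segments, ncol(stress_profile) == 3,
            all(stress_profile >= 0), all(stress_profile <= 1))
  colnames(stress_profile) <- c("vibration", "encounters", "width")
  structure(list(
    route_length = route_length, segment_interval = segment_interval,
    n_segments = n_segments, speed_mean = speed_mean,
    gps_noise_sd = gps_noise_sd, gps_gap_spec = gps_gap_spec,
    stress_profile = stress_profile, stationary_s = stationary_s,
    rri_baseline_mean = rri_baseline_mean, rri_sdnn_low = rri_sdnn_low,
    rri_sdnn_high = rri_sdnn_high, artifact_rates = artifact_rates,
    vib_floor = vib_floor, vib_slope = vib_slope,
    encounter_scale = encounter_scale, seed = as.integer(seed)
  ), class = "ride_config")
}

#' Generate a loop route polyline
#'
#' A closed, gently wobbled loop anchored in an urban coordinate frame whose
#' cumulative geodesic length matches `route_length` to within 0.1%
#' (enforced by iterative rescaling of the loop radius).
#'
#' @param config A [ride_config()].
#' @return Data frame of ordered `lat`/`lon` vertices (~5 m spacing).
#' @export
generate_route <- function(config) {
  stopifnot(inherits(config, "ride_config"))
  substream(config, 1L)
  center <- c(lat = 35.66, lon = 139.79)
  n_pts <- max(64, ceiling(config$route_length / 5))
  theta <- seq(0, 2 * pi, length.out = n_pts + 1)[-(n_pts + 1)]
  phase <- runif(2, 0, 2 * pi)
  wobble <- 1 + 0.05 * sin(2 * theta + phase[1]) + 0.03 * sin(3 * theta + phase[2])
  radius <- config$route_length / (2 * pi)
  build <- function(radius) {
    r <- radius * wobble
    d_north <- r * cos(theta)
    d_east <- r * sin(theta)
    lat <- center["lat"] + d_north / EARTH_RADIUS_M * 180 / pi
    lon <- center["lon"] + d_east /
      (EARTH_RADIUS_M * cos(center["lat"] * pi / 180)) * 180 / pi
    data.frame(lat = c(lat, lat[1]), lon = c(lon, lon[1]))
  }
  # converge the radius, then land just above the target length so the
  # route supports exactly floor(length / interval) whole segments
  for (iter in 1:6) {
    route <- build(radius)
    total <- route_chainage(route)[nrow(route)]
    if (abs(total - config$route_length) / config$route_length < 1e-5) break
    radius <- radius * config$route_length / total
  }
  route <- build(radius * (1 + 2e-5))
  rownames(route) <- NULL
  route
}

# Per-second speed profile and boundary passage times (truth).
# Returns list(speeds [m/s at seconds stationary_s..], passage_times).
ride_motion <- function(config) {
  substream(config, 2L)
  cap <- 6 / 3.6
  total <- config$route_length
  # generous horizon, trimmed to the ride end
  n_max <- ceiling(total / (0.5 * config$speed_mean)) + config$stationary_s
  speeds <- pmin(pmax(rnorm(n_max, config$speed_mean, 0.12 * config$speed_mean),
                      0.3), cap)
  chain <- cumsum(speeds)
  n_ride <- which(chain >= total)[1]
  if (is.na(n_ride)) stop("speed profile did not cover the route")
  speeds <- speeds[seq_len(n_ride)]
  chain <- c(0, chain[seq_len(n_ride)])
  bounds <- (0:config$n_segments) * config$segment_interval
  # linear interpolation of the crossing time within the second
  passage <- vapply(bounds, function(b) {
    j <- which(chain >= b - 1e-9)[1]
    if (j == 1) return(0)
    (j - 2) + (b - chain[j - 1]) / (chain[j] - chain[j - 1])
  }, numeric(1))
  list(speeds = speeds, chain = chain,
       passage_times = config$stationary_s + passage,
       ride_end = config$stationary_s + n_ride)
}

#' Generate a 1 Hz GPS track along the route
#'
#' Fixes at integer seconds: a stationary lead-in at the route origin, then
#' travel along the route at a seeded per-second speed profile capped at
#' 6 km/h, with isotropic Gaussian position noise and dropouts per
#' `gps_gap_spec`. The noise-free path and the true boundary passage times
#' are attached as attributes `path` and `passage_times`.
#'
#' @param route Polyline from [generate_route()].
#' @param config A [ride_config()].
#' @return Data frame of fixes (`timestamp`, `lat`, `lon`, `speed`,
#'   `accuracy`).
#' @export
generate_gps_track <- function(route, config) {
  motion <- ride_motion(config)
  t_ride <- seq_along(motion$speeds) + config$stationary_s - 1
  chain_at_fix <- pmin(motion$chain[seq_along(motion$speeds)],
                       config$route_length)
  pos <- point_at_chainage(route, chain_at_fix)
  ts <- c(seq_len(config$stationary_s) - 1, t_ride)
  path <- data.frame(
    timestamp = ts,
    lat = c(rep(route$lat[1], config$stationary_s), pos$lat),
    lon = c(rep(route$lon[1], config$stationary_s), pos$lon),
    speed = c(rep(0, config$stationary_s), motion$speeds)
  )
  substream(config, 3L)
  n <- nrow(path)
  north <- rnorm(n, 0, config$gps_noise_sd)
  east <- rnorm(n, 0, config$gps_noise_sd)
  fixes <- data.frame(
    timestamp = path$timestamp,
    lat = path$lat + north / EARTH_RADIUS_M * 180 / pi,
    lon = path$lon + east / (EARTH_RADIUS_M * cos(path$lat * pi / 180)) * 180 / pi,
    speed = path$speed,
    accuracy = pmax(abs(rnorm(n, 5, 2)), 1)
  )
  for (gap in config$gps_gap_spec) {
    fixes <- fixes[!(fixes$timestamp >= gap[1] &
                       fixes$timestamp < gap[1] + gap[2]), ]
  }
  rownames(fixes) <- NULL
  attr(fixes, "path") <- path
  attr(fixes, "passage_times") <- motion$passage_times
  attr(fixes, "ride_end") <- motion$ride_end
  fixes
}

# segment index (1..n_segments) at each time, 0 outside the ride
segment_at_time <- function(t, passage_times) {
  idx <- findInterval(t, passage_times)
  idx[idx > length(passage_times) - 1] <- 0L
  idx
}

#' Generate environment streams coupled to the stress profile
#'
#' Produces 100 Hz tri-axial acceleration (gravity plus mounting offset on
#' the vertical y axis; band-limited 0.5-45 Hz vibration noise whose
#' amplitude grows linearly with the segment's vibration intensity), 0.5 Hz
#' environmental channels inside their sensor ranges, a Poisson
#' unique-person encounter stream scaled by encounter intensity, and a
#' sidewalk-width map that narrows with width intensity.
#'
#' @param route Polyline from [generate_route()].
#' @param config A [ride_config()].
#' @param passage_times True boundary passage times (attribute of
#'   [generate_gps_track()] output).
#' @return List `accel`, `env`, `encounters`, `widths`.
#' @export
generate_environment <- function(route, config, passage_times) {
  ride_end <- ceiling(passage_times[length(passage_times)])
  intensities <- config$stress_profile

  # --- acceleration, 100 Hz ---
  substream(config, 4L)
  t <- seq(0, ride_end, by = 0.01)
  seg <- segment_at_time(t, passage_times)
  sigma <- config$vib_floor +
    ifelse(seg == 0, 0, config$vib_slope * intensities[pmax(seg, 1), "vibration"])
  vib <- bandlimit(rnorm(length(t)), fs = 100, low = 0.5, high = 45) * sigma
  accel <- data.frame(
    timestamp = t,
    x = 0.04 + rnorm(length(t), 0, 0.03),
    y = 9.81 + 0.12 + vib,
    z = -0.06 + rnorm(length(t), 0, 0.03)
  )

  # --- environmental channels, 0.5 Hz ---
  substream(config, 5L)
  te <- seq(0, ride_end, by = 2)
  env <- rbind(
    data.frame(timestamp = te, channel = "noise_db",
               value = pmin(pmax(rnorm(length(te), 58, 4), 31), 129)),
    data.frame(timestamp = te, channel = "temperature",
               value = pmin(pmax(rnorm(length(te), 24, 0.5), 1), 49)),
    data.frame(timestamp = te, channel = "humidity",
               value = pmin(pmax(rnorm(length(te), 55, 2), 1), 94)),
    data.frame(timestamp = te, channel = "wind",
               value = pmin(pmax(rnorm(length(te), 2, 0.6), 0.4), 24.9)),
    data.frame(timestamp = te, channel = "illuminance",
               value = pmin(pmax(rnorm(length(te), 9000, 1500), 10), 19990))
  )
  env <- env[order(env$timestamp, env$channel), ]
  rownames(env) <- NULL

  # --- unique-person encounters, Poisson per segment ---
  substream(config, 6L)
  enc_rows <- list()
  next_id <- 1L
  for (s in seq_len(config$n_segments)) {
    lambda <- config$encounter_scale * intensities[s, "encounters"]
    n_persons <- if (lambda == 0) 0L else rpois(1, lambda)
    if (n_persons == 0) next
    t0 <- passage_times[s]
    t1 <- passage_times[s + 1]
    for (p in seq_len(n_persons)) {
      first <- runif(1, t0, t1 - 1e-6)
      sightings <- sort(c(first, first + runif(rpois(1, 2), 0, 3)))
      enc_rows[[length(enc_rows) + 1]] <- data.frame(
        time = sightings, person_id = next_id)
      next_id <- next_id + 1L
    }
  }
  encounters <- if (length(enc_rows)) do.call(rbind, enc_rows) else {
    data.frame(time = numeric(), person_id = integer())
  }
  encounters <- encounters[order(encounters$time, encounters$person_id), ]
  rownames(encounters) <- NULL

  # --- sidewalk-width map, 25 m pieces ---
  substream(config, 7L)
  piece <- 25
  starts <- seq(0, config$route_length - 1e-9, by = piece)
  seg_of_piece <- pmin(floor(starts / config$segment_interval) + 1,
                       config$n_segments)
  widths <- data.frame(
    chainage_start_m = starts,
    chainage_end_m = pmin(starts + piece, config$route_length),
    width_m = pmax(3.5 - 2.7 * intensities[seg_of_piece, "width"] +
                     runif(length(starts), -0.1, 0.1), 0.5)
  )

  list(accel = accel, env = env, encounters = encounters, widths = widths)
}

#' Generate a beat-timestamped RRI series with stress-coupled variability
#'
#' Clean RR intervals follow a standardized AR(1) fluctuation (lag-1
#' autocorrelation 0.9, emulating the smooth beat-to-beat structure of real
#' heart-rate variability) around the participant baseline, scaled to a
#' within-segment SDNN set by the segment's true stress level
#' (`rri_sdnn_high` when Low, `rri_sdnn_low` when High, midway when
#' Moderate); the stationary lead-in uses the relaxed SDNN. Ectopic beats
#' (values outside 300-1300 ms) and spike artifacts (15-35% abrupt changes)
#' are then injected at `artifact_rates`. The pre-corruption series is
#' returned as the cleaning oracle.
#'
#' @param config A [ride_config()].
#' @param truth Ground truth from [ride_ground_truth()] (supplies
#'   `passage_times` and per-segment `suppression`).
#' @param participant Participant number; offsets the RNG substream and the
#'   baseline mean so participants differ.
#' @return List: `series` (corrupted data frame `beat_time`/`rri_ms`),
#'   `clean` (artifact-free oracle), `injected_fraction`,
#'   `injected_idx`, `baseline_mean`.
#' @export
generate_rri <- function(config, truth, participant = 1) {
  substream(config, 100L + participant)
  baseline <- config$rri_baseline_mean + rnorm(1, 0, 60)
  ride_end <- truth$passage_times[length(truth$passage_times)]
  sdnn_seg <- config$rri_sdnn_high * truth$suppression
  phi <- 0.9
  n_est <- ceiling(ride_end * 1000 / max(baseline - 4 * config$rri_sdnn_high,
                                         400)) + 16
  eps <- rnorm(n_est)
  rr <- numeric(n_est)
  u <- eps[1] # standardized AR(1) state, marginal N(0, 1)
  t <- 0
  i <- 0
  while (t < ride_end && i < n_est) {
    i <- i + 1
    if (i > 1) u <- phi * u + sqrt(1 - phi^2) * eps[i]
    s <- segment_at_time(t, truth$passage_times)
    sdnn_t <- if (s == 0) config$rri_sdnn_high else sdnn_seg[s]
    beat <- min(max(baseline + sdnn_t * u, 400), 1290)
    rr[i] <- beat
    t <- t + beat / 1000
  }
  rr <- rr[seq_len(i)]
  beat_time <- cumsum(rr) / 1000
  clean <- data.frame(beat_time = beat_time, rri_ms = rr)

  n <- length(rr)
  n_ect <- round(config$artifact_rates[["ectopic"]] * n)
  n_spk <- round(config$artifact_rates[["spike"]] * n)
  idx <- sample.int(n, n_ect + n_spk)
  corrupted <- rr
  if (n_ect > 0) {
    ie <- idx[seq_len(n_ect)]
    short <- runif(length(ie)) < 0.5
    corrupted[ie] <- ifelse(short, runif(length(ie), 150, 280),
                            runif(length(ie), 1350, 1800))
  }
  if (n_spk > 0) {
    is_ <- idx[n_ect + seq_len(n_spk)]
    sign_ <- ifelse(runif(length(is_)) < 0.5, -1, 1)
    corrupted[is_] <- pmin(pmax(
      corrupted[is_] * (1 + sign_ * runif(length(is_), 0.15, 0.35)), 310), 1290)
  }
  series <- data.frame(beat_time = cumsum(corrupted) / 1000, rri_ms = corrupted)
  list(series = series, clean = clean,
       injected_fraction = (n_ect + n_spk) / n,
       injected_idx = sort(idx), baseline_mean = baseline)
}

#' Ground truth for a synthetic ride
#'
#' True factor levels are the tertile classification of the true intensity
#' triples (the same rule the pipeline applies to measured values; with the
#' default well-separated intensities this coincides with absolute thirds of
#' \[0, 1\]). True CSS and stress labels follow by applying the scoring
#' module to those levels, and the per-segment HRV suppression factor maps
#' the label to `1` (Low), the midpoint (Moderate), or
#' `rri_sdnn_low / rri_sdnn_high` (High).
#'
#' @param config A [ride_config()].
#' @param passage_times True boundary passage times.
#' @return List: `passage_times`, `levels` (tidy factor levels), `css`
#'   (per-segment CSS records), `suppression` (per-segment factor).
#' @export
ride_ground_truth <- function(config, passage_times) {
  prof <- config$stress_profile
  lv <- function(x, dir) classify_tertiles(x, dir)
  levels <- rbind(
    data.frame(segment_id = seq_len(config$n_segments), factor = "vibration_rms",
               level = lv(prof[, "vibration"], 1)),
    data.frame(segment_id = seq_len(config$n_segments), factor = "encounter_count",
               level = lv(prof[, "encounters"], 1)),
    data.frame(segment_id = seq_len(config$n_segments), factor = "sidewalk_width",
               level = lv(1 - prof[, "width"], -1))
  )
  css <- compute_css(levels)
  css <- css[order(css$segment_id), ]
  low_f <- config$rri_sdnn_low / config$rri_sdnn_high
  suppression <- c(Low = 1, Moderate = (1 + low_f) / 2, High = low_f)[css$stress_level]
  list(passage_times = passage_times, levels = levels, css = css,
       suppression = unname(suppression))
}

#' Generate a complete synthetic ride
#'
#' Orchestrates route, GPS, environment, ground truth, and per-participant
#' RRI generation from one seeded configuration.
#'
#' @param config A [ride_config()].
#' @param participants Number of RRI series to generate (default 1); 0 skips
#'   RRI generation.
#' @param signals Which signal groups to generate: any of `"gps"`,
#'   `"environment"`, `"rri"` (GPS is always generated; it defines the
#'   ground-truth timing).
#' @return An `lmd_ride` list: `config`, `route`, `gps`, `accel`, `env`,
#'   `encounters`, `widths`, `rri` (list per participant), `truth`.
#' @export
generate_ride <- function(config, participants = 1,
                          signals = c("gps", "environment", "rri")) {
  stopifnot(inherits(config, "ride_config"))
  route <- generate_route(config)
  gps <- generate_gps_track(route, config)
  truth <- ride_ground_truth(config, attr(gps, "passage_times"))
  ride <- list(config = config, route = route, gps = gps, truth = truth,
               accel = NULL, env = NULL, encounters = NULL, widths = NULL,
               rri = NULL)
  if ("environment" %in% signals) {
    environ <- generate_environment(route, config, truth$passage_times)
    ride[c("accel", "env", "encounters", "widths")] <- environ
  }
  if ("rri" %in% signals && participants > 0) {
    ride$rri <- lapply(seq_len(participants), function(p) {
      generate_rri(config, truth, participant = p)
    })
  }
  class(ride) <- "lmd_ride"
  ride
}
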