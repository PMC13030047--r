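# Shared fixtures, built in code.

# meridian line of the given length (metres), vertices every `step` m
meridian_route <- function(length_m, step = 50) {
  deg_per_m <- 180 / (pi * 6371000)
  s <- seq(0, length_m, by = step)
  if (tail(s, 1) < length_m) s <- c(s, length_m)
  data.frame(lat = s * deg_per_m, lon = 0)
}

# independent arc-length oracle: cumulative haversine along a lat/lon path
arc_length <- function(lat, lon) {
  n <- length(lat)
  sum(geosphere::distHaversine(cbind(lon[-n], lat[-n]),
                               cbind(lon[-1], lat[-1]), r = 6371000))
}

# small ride for fast tests: 600 m loop, 6 segments
small_ride_config <- function(seed = 1, ...) {
  ride_config(route_length = 600, segment_interval = 100, seed = seed, ...)
}

# brute-force time-domain HRV oracle (plain loops, independent of the
# vectorized implementation)
oracle_hrv <- function(rr) {
  n <- length(rr)
  m <- sum(rr) / n
  ss <- 0
  for (v in rr) ss <- ss + (v - m)^2
  sdnn <- sqrt(ss / (n - 1))
  sd2 <- 0
  n50 <- 0
  for (i in seq_len(n - 1)) {
    d <- rr[i + 1] - rr[i]
    sd2 <- sd2 + d^2
    if (abs(d) > 50) n50 <- n50 + 1
  }
  list(sdnn = sdnn, rmssd = sqrt(sd2 / (n - 1)), pnn50 = 100 * n50 / (n - 1))
}
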