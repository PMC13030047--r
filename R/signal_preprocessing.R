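#' Sensor measurement ranges for the environmental channels
#'
#' Physical measurement ranges of the onboard sensors; values outside these
#' limits are treated as anomalous and removed by [clean_env_stream()].
#'
#' @return Named list of `c(min, max)` per channel.
#' @export
env_channel_ranges <- function() {
  list(
    noise_db    = c(30, 130),     # sound level meter, dB
    temperature = c(0, 50),       # deg C
    humidity    = c(0, 95),       # % RH
    wind        = c(0.4, 25),     # m/s
    illuminance = c(0, 20000)     # lux
  )
}

#' Remove out-of-range environmental samples
#'
#' Samples exceeding the physical limits of the recording sensor's measurement
#' range are anomalous and dropped. The operation is idempotent.
#'
#' @param samples Data frame with columns `timestamp`, `channel`, `value`.
#' @param ranges Named list of `c(min, max)` per channel
#'   (default [env_channel_ranges()]).
#' @return Filtered data frame; the number of removed rows is reported via
#'   `message()` and attached as attribute `n_removed`.
#' @export
clean_env_stream <- function(samples, ranges = env_channel_ranges()) {
  stopifnot(all(c("timestamp", "channel", "value") %in% names(samples)))
  unknown <- setdiff(unique(samples$channel), names(ranges))
  if (length(unknown)) stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  keep <- vapply(seq_len(nrow(samples)), function(i) {
    r <- ranges[[samples$channel[i]]]
    v <- samples$value[i]
    is.finite(v) && v >= r[1] && v <= r[2]
  }, logical(1))
  out <- samples[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (n_removed > 0) message("clean_env_stream: removed ", n_removed,
                             " of ", nrow(samples), " samples")
  if (nrow(out) == 0) warning("all environmental samples removed")
  rownames(out) <- NULL
  attr(out, "n_removed") <- n_removed
  out
}

#' Resample a GPS trajectory to a uniform 1 Hz grid
#'
#' Fixes are snapped to integer seconds; short gaps (at most `gap_max`
#' seconds) are filled by great-circle interpolation between the flanking
#' fixes, equally spaced in time, with linearly interpolated speed. Longer
#' gaps are left missing and flagged `excluded`.
#'
#' @param fixes Data frame with columns `timestamp` (seconds), `lat`, `lon`,
#'   and optionally `speed`, `accuracy`; sorted, deduplicated, no missing
#'   coordinates.
#' @param gap_max Longest gap (s) that is interpolated (default 10).
#' @return Data frame on the uniform grid with logical columns `interpolated`
#'   and `excluded`. First and last fix timestamps are preserved.
#' @export
resample_gps <- function(fixes, gap_max = 10) {
  stopifnot(nrow(fixes) >= 2, !anyNA(fixes$lat), !anyNA(fixes$lon),
            !is.unsorted(fixes$timestamp, strictly = TRUE))
  ts <- round(fixes$timestamp)
  grid <- seq(ts[1], ts[length(ts)], by = 1)
  idx <- match(grid, ts)
  out <- data.frame(
    timestamp = grid,
    lat = fixes$lat[idx], lon = fixes$lon[idx],
    speed = if ("speed" %in% names(fixes)) fixes$speed[idx] else NA_real_,
    accuracy = if ("accuracy" %in% names(fixes)) fixes$accuracy[idx] else NA_real_,
    interpolated = FALSE, excluded = FALSE
  )
  miss <- which(is.na(out$lat))
  if (length(miss)) {
    runs <- split(miss, cumsum(c(1, diff(miss) != 1)))
    for (run in runs) {
      a <- run[1] - 1
      b <- run[length(run)] + 1
      if (length(run) <= gap_max) {
        pts <- gc_interpolate(out$lat[a], out$lon[a], out$lat[b], out$lon[b],
                              n = length(run))
        out$lat[run] <- pts$lat
        out$lon[run] <- pts$lon
        f <- seq_along(run) / (length(run) + 1)
        out$speed[run] <- out$speed[a] + f * (out$speed[b] - out$speed[a])
        out$interpolated[run] <- TRUE
      } else {
        out$excluded[run] <- TRUE
      }
    }
  }
  out
}

# Zero-phase band-pass realized as a cascade of 4th-order Butterworth
# high-pass and low-pass sections, each applied forward-backward. The
# cascade is numerically stable where a single 8-pole band-pass in
# transfer-function form is not (the 0.5 Hz edge sits at 1% of Nyquist).
bandlimit <- function(x, fs, low, high) {
  hp <- signal::butter(4, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  # remove the mean first: the high-pass kills DC anyway, and a large offset
  # (gravity) would otherwise excite long edge transients in filtfilt
  x <- x - mean(x)
  as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, x)))
}

#' Zero-phase band-pass filter for acceleration streams
#'
#' 4th-order Butterworth filtering to the 0.5-45 Hz pass-band (high-pass and
#' low-pass sections in cascade) applied forward-backward, removing
#' low-frequency drift (including the gravity DC component) and
#' high-frequency noise without phase shift.
#'
#' @param samples Data frame with columns `timestamp`, `x`, `y`, `z`; sampling
#'   rate is inferred from the timestamps.
#' @param low,high Pass-band edges in Hz.
#' @return `samples` with filtered axis columns.
#' @export
bandpass_accel <- function(samples, low = 0.5, high = 45) {
  stopifnot(all(c("timestamp", "x", "y", "z") %in% names(samples)), low < high)
  fs <- 1 / median(diff(samples$timestamp))
  if (fs <= 2 * high) {
    stop("sampling rate ", round(fs, 1), " Hz too low for a ", high, " Hz band edge")
  }
  for (ax in c("x", "y", "z")) {
    samples[[ax]] <- bandlimit(samples[[ax]], fs, low, high)
  }
  samples
}

# Auto-detect a stationary window from GPS speed: first run of speed below
# speed_thresh lasting at least min_len seconds. Returns c(start, end) or NULL.
detect_stationary_window <- function(gps, speed_thresh = 0.1, min_len = 10) {
  slow <- !is.na(gps$speed) & gps$speed < speed_thresh
  if (!any(slow)) return(NULL)
  runs <- rle(slow)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ok <- which(runs$values & runs$lengths >= min_len)
  if (!length(ok)) return(NULL)
  c(gps$timestamp[starts[ok[1]]], gps$timestamp[ends[ok[1]]])
}

#' Offset-correct acceleration using a stationary period
#'
#' Subtracts the per-axis mean acceleration observed while the vehicle is
#' stationary from the whole record, removing device-mounting offsets (and,
#' for unfiltered data, gravity on the vertical axis).
#'
#' @param samples Acceleration data frame (`timestamp`, `x`, `y`, `z`).
#' @param stationary_window Numeric `c(start, end)` in seconds, or NULL to
#'   auto-detect from `gps` (speed < 0.1 m/s sustained for >= 10 s).
#' @param gps Optional resampled GPS data frame used for auto-detection.
#' @return Corrected samples; the subtracted offsets are attached as
#'   attribute `offset`.
#' @export
offset_correct <- function(samples, stationary_window = NULL, gps = NULL) {
  if (is.null(stationary_window)) {
    if (!is.null(gps)) stationary_window <- detect_stationary_window(gps)
    if (is.null(stationary_window)) {
      stop("no stationary period found; supply stationary_window = c(start, end)")
    }
  }
  stopifnot(length(stationary_window) == 2,
            stationary_window[1] < stationary_window[2])
  in_win <- samples$timestamp >= stationary_window[1] &
    samples$timestamp < stationary_window[2]
  if (!any(in_win)) stop("no acceleration samples inside the stationary window")
  offset <- c(x = mean(samples$x[in_win]), y = mean(samples$y[in_win]),
              z = mean(samples$z[in_win]))
  samples$x <- samples$x - offset[["x"]]
  samples$y <- samples$y - offset[["y"]]
  samples$z <- samples$z - offset[["z"]]
  attr(samples, "offset") <- offset
  samples
}

#' Per-second RMS of vertical acceleration
#'
#' Root mean square of the designated vertical axis over non-overlapping 1 s
#' windows aligned to integer seconds. Windows holding fewer than half the
#' expected number of samples yield NA.
#'
#' @param samples Offset-corrected, band-passed acceleration data frame.
#' @param axis Vertical axis column; `"y"` under the standard mounting
#'   convention (y up).
#' @return Data frame with columns `timestamp` (window start, s) and `rms`
#'   (m/s^2).
#' @export
vertical_rms <- function(samples, axis = "y") {
  stopifnot(axis %in% names(samples))
  fs <- 1 / median(diff(samples$timestamp))
  sec <- floor(samples$timestamp)
  v2 <- samples[[axis]]^2
  n <- tapply(v2, sec, length)
  ms <- tapply(v2, sec, mean)
  rms <- sqrt(ms)
  rms[n < fs / 2] <- NA_real_
  data.frame(timestamp = as.numeric(names(rms)), rms = as.numeric(rms),
             row.names = NULL)
}

#' Count unique persons first encountered within a segment
#'
#' Each tracked person carries a stable unique ID; a person is attributed to
#' the segment in which they are first seen, so no individual is counted
#' twice across segments.
#'
#' @param stream Data frame with columns `time`, `person_id`.
#' @param segment One-row segment data frame with `entry_time`, `exit_time`
#'   (window is half-open `[entry, exit)`).
#' @return Integer count.
#' @export
count_encounters <- function(stream, segment) {
  if (nrow(stream) == 0) return(0L)
  first_seen <- tapply(stream$time, stream$person_id, min)
  sum(first_seen >= segment$entry_time & first_seen < segment$exit_time)
}
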