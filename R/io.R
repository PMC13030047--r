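# Readers and writers for the on-disk ride bundle. Column dialects:
#   gps.csv              time, latitude, longitude, speed, accuracy  (1 Hz)
#   accel.csv            time, x, y, z                               (100 Hz)
#   env.csv              time, channel, value                        (0.5 Hz)
#   encounters.csv       time, person_id
#   sidewalk_widths.csv  chainage_start_m, chainage_end_m, width_m
#   rri_<p>.csv          beat_time, rri_ms
#   route.geojson        GeoJSON LineString (WGS84 lon/lat)
#   ground_truth.json    generator sidecar (synthetic rides only)

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file ", file, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
}

read_numeric_time <- function(x, file) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    stop("unparseable timestamp(s) in ", file, " at row(s) ",
         paste(head(which(is.na(v)), 5), collapse = ", "))
  }
  v
}

#' Write a ride bundle to a directory
#'
#' Writes the CSV/GeoJSON dialects the pipeline reads; for synthetic rides
#' the ground truth is stored in a separate JSON sidecar.
#'
#' @param ride An `lmd_ride` list (see [generate_ride()]) or a compatible
#'   bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ride <- function(ride, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) write.csv(df, file.path(dir, name), row.names = FALSE)
  w(data.frame(time = ride$gps$timestamp, latitude = ride$gps$lat,
               longitude = ride$gps$lon, speed = ride$gps$speed,
               accuracy = ride$gps$accuracy), "gps.csv")
  if (!is.null(ride$accel)) {
    w(data.frame(time = ride$accel$timestamp, x = ride$accel$x,
                 y = ride$accel$y, z = ride$accel$z), "accel.csv")
  }
  if (!is.null(ride$env)) {
    w(data.frame(time = ride$env$timestamp, channel = ride$env$channel,
                 value = ride$env$value), "env.csv")
  }
  if (!is.null(ride$encounters)) w(ride$encounters, "encounters.csv")
  if (!is.null(ride$widths)) w(ride$widths, "sidewalk_widths.csv")
  if (!is.null(ride$rri)) {
    for (p in seq_along(ride$rri)) {
      w(ride$rri[[p]]$series, sprintf("rri_%02d.csv", p))
    }
  }
  route_gj <- list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = unname(as.matrix(ride$route[, c("lon", "lat")]))),
    properties = list(name = "route")
  )
  jsonlite::write_json(route_gj, file.path(dir, "route.geojson"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(ride$truth)) {
    truth <- ride$truth
    jsonlite::write_json(
      list(passage_times = truth$passage_times, levels = truth$levels,
           css = truth$css,
           suppression = truth$suppression,
           stress_profile = unname(ride$config$stress_profile)),
      file.path(dir, "ground_truth.json"), digits = NA)
  }
  invisible(dir)
}

#' Read a ride bundle from a directory
#'
#' Parses and validates the sensor streams written by [write_ride()] (or
#' prepared externally in the same dialect). Timestamps are shifted by
#' `tz_offset` onto the unified clock and each stream is sorted. GPS rows
#' missing latitude or longitude are dropped with a message; missing
#' mandatory columns or unparseable timestamps are rejected.
#'
#' @param dir Directory holding the bundle.
#' @param tz_offset Seconds added to every timestamp (default 0).
#' @return An `lmd_ride`-like list (with `truth` when the sidecar exists).
#' @export
read_ride <- function(dir, tz_offset = 0) {
  path <- function(name) file.path(dir, name)
  if (!file.exists(path("gps.csv"))) stop("gps.csv not found in ", dir)

  gps_raw <- read.csv(path("gps.csv"))
  require_columns(gps_raw, c("time", "latitude", "longitude"), "gps.csv")
  drop <- is.na(gps_raw$latitude) | is.na(gps_raw$longitude)
  if (any(drop)) {
    message("read_ride: dropped ", sum(drop), " GPS row(s) missing coordinates")
    gps_raw <- gps_raw[!drop, ]
  }
  gps <- data.frame(
    timestamp = read_numeric_time(gps_raw$time, "gps.csv") + tz_offset,
    lat = gps_raw$latitude, lon = gps_raw$longitude,
    speed = if ("speed" %in% names(gps_raw)) gps_raw$speed else NA_real_,
    accuracy = if ("accuracy" %in% names(gps_raw)) gps_raw$accuracy else NA_real_
  )
  gps <- gps[order(gps$timestamp), ]
  gps <- gps[!duplicated(gps$timestamp), ]
  rownames(gps) <- NULL

  read_opt <- function(name, cols, rename = identity) {
    if (!file.exists(path(name))) return(NULL)
    df <- read.csv(path(name))
    require_columns(df, cols, name)
    rename(df)
  }
  accel <- read_opt("accel.csv", c("time", "x", "y", "z"), function(df) {
    out <- data.frame(timestamp = read_numeric_time(df$time, "accel.csv") + tz_offset,
                      x = df$x, y = df$y, z = df$z)
    out[order(out$timestamp), ]
  })
  env <- read_opt("env.csv", c("time", "channel", "value"), function(df) {
    out <- data.frame(timestamp = read_numeric_time(df$time, "env.csv") + tz_offset,
                      channel = df$channel, value = df$value)
    out[order(out$timestamp, out$channel), ]
  })
  encounters <- read_opt("encounters.csv", c("time", "person_id"), function(df) {
    df$time <- read_numeric_time(df$time, "encounters.csv") + tz_offset
    df[order(df$time, df$person_id), ]
  })
  widths <- read_opt("sidewalk_widths.csv",
                     c("chainage_start_m", "chainage_end_m", "width_m"),
                     identity)

  rri_files <- sort(list.files(dir, pattern = "^rri_[0-9]+\\.csv$"))
  rri <- if (length(rri_files)) {
    lapply(rri_files, function(f) {
      df <- read.csv(path(f))
      require_columns(df, c("beat_time", "rri_ms"), f)
      df$beat_time <- read_numeric_time(df$beat_time, f) + tz_offset
      list(series = df[order(df$beat_time), ])
    })
  } else NULL

  gj <- jsonlite::read_json(path("route.geojson"), simplifyVector = TRUE)
  coords <- gj$geometry$coordinates
  route <- data.frame(lat = coords[, 2], lon = coords[, 1])

  truth <- if (file.exists(path("ground_truth.json"))) {
    jsonlite::read_json(path("ground_truth.json"), simplifyVector = TRUE)
  } else NULL

  list(route = route, gps = gps, accel = accel, env = env,
       encounters = encounters, widths = widths, rri = rri, truth = truth)
}
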