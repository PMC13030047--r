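#' Place segment boundaries at fixed chainage intervals along a route
#'
#' Walks the route polyline and drops a boundary point every `interval` metres
#' of cumulative geodesic distance, starting at the route origin (boundary
#' index 0). A trailing remainder shorter than `interval` yields no boundary,
#' so all resulting segments have equal length.
#'
#' @param route Data frame with columns `lat`, `lon` (WGS84 degrees), ordered
#'   along the direction of travel; at least 2 distinct points.
#' @param interval Segment length in metres (default 100).
#' @return Data frame with columns `index` (0-based), `lat`, `lon`,
#'   `chainage` (metres, equal to `index * interval`).
#' @examples
#' route <- data.frame(lat = c(0, 0.0027), lon = 0) # ~300 m meridian line
#' chainage(route, 100)
#' @export
chainage <- function(route, interval = 100) {
  stopifnot(is.data.frame(route), all(c("lat", "lon") %in% names(route)),
            interval > 0)
  cum <- route_chainage(route)
  total <- cum[length(cum)]
  if (total < interval) {
    stop("route length (", round(total, 1), " m) is shorter than the segment interval")
  }
  k <- floor(total / interval + 1e-9)
  s <- (0:k) * interval
  s <- s[s <= total + 1e-6]
  pts <- point_at_chainage(route, pmin(s, total))
  data.frame(index = seq_along(s) - 1L, lat = pts$lat, lon = pts$lon,
             chainage = s)
}

#' Match segment boundaries to the nearest GPS fix
#'
#' For each boundary point the GPS fix at minimum geodesic distance is taken
#' as the match point and its timestamp becomes the boundary passage time.
#' Equidistant fixes are resolved to the earliest timestamp. Because a
#' traversed route passes its boundaries in order, matched times must be
#' strictly increasing; when the raw nearest-fix matches violate this (GPS
#' noise, or a loop route whose start is revisited at the end), the
#' boundaries are re-matched, with a warning, by the monotone assignment
#' minimizing the total match distance (boundaries whose admissible fixes
#' all lie beyond the rejection radius stay unmatched).
#'
#' @param boundaries Data frame from [chainage()].
#' @param fixes Data frame of preprocessed GPS fixes with columns `timestamp`
#'   (seconds, strictly increasing), `lat`, `lon`.
#' @param reject_radius Boundaries whose nearest admissible fix lies farther
#'   than this (metres) are flagged unmatched (default 50).
#' @param enforce_monotone Repair non-monotone match times (default TRUE).
#' @return `boundaries` with added columns `matched_time` (NA if unmatched)
#'   and `match_distance` (metres).
#' @export
match_boundaries <- function(boundaries, fixes, reject_radius = 50,
                             enforce_monotone = TRUE) {
  stopifnot(nrow(fixes) >= 1, !is.unsorted(fixes$timestamp, strictly = TRUE))
  nb <- nrow(boundaries)
  nf <- nrow(fixes)
  d <- matrix(0, nb, nf)
  for (b in seq_len(nb)) {
    d[b, ] <- geodesic_distance(boundaries$lat[b], boundaries$lon[b],
                                fixes$lat, fixes$lon)
  }
  # unconstrained nearest fix, earliest timestamp on ties
  pick <- apply(d, 1, which.min)
  dist_raw <- d[cbind(seq_len(nb), pick)]
  pick[dist_raw > reject_radius] <- NA
  times_raw <- fixes$timestamp[pick]
  monotone <- !is.unsorted(times_raw[!is.na(times_raw)], strictly = TRUE)

  if (!enforce_monotone || monotone) {
    matched_time <- times_raw
    match_dist <- ifelse(is.na(pick), NA_real_, dist_raw)
  } else {
    warning("non-monotone boundary match times; re-matched by monotone ",
            "minimum-distance assignment")
    assign <- monotone_assignment(d, penalty = reject_radius)
    matched_time <- fixes$timestamp[assign]
    match_dist <- d[cbind(seq_len(nb), assign)]
  }
  boundaries$matched_time <- matched_time
  boundaries$match_distance <- match_dist
  boundaries
}

# Monotone boundary-to-fix assignment minimizing total distance by dynamic
# programming. Fix indices must be strictly increasing across matched
# boundaries; leaving a boundary unmatched costs `penalty` (so fixes farther
# than the rejection radius never beat staying unmatched). Ties resolve to
# the earliest fix. Returns a vector of fix indices (NA = unmatched).
monotone_assignment <- function(d, penalty) {
  nb <- nrow(d)
  nf <- ncol(d)
  choice <- matrix(0L, nb, nf) # 1 = carry from f-1, 2 = match f, 3 = skip boundary
  prev <- rep(0, nf + 1) # dp row, index f+1 = using fixes 1..f
  for (b in seq_len(nb)) {
    cand_match <- prev[seq_len(nf)] + d[b, ]
    cand_skip <- prev[-1] + penalty
    base <- pmin(cand_match, cand_skip)
    ch <- ifelse(cand_match <= cand_skip, 2L, 3L)
    cur <- cummin(c(prev[1] + penalty, base))
    carried <- cur[-1] < base | c(FALSE, cur[-1][-1] == cur[-1][-nf])
    ch[carried] <- 1L
    choice[b, ] <- ch
    prev <- cur
  }
  assign <- rep(NA_integer_, nb)
  f <- nf
  b <- nb
  while (b >= 1) {
    if (f == 0) { b <- b - 1; next }
    step <- choice[b, f]
    if (step == 1L) f <- f - 1
    else if (step == 2L) { assign[b] <- f; f <- f - 1; b <- b - 1 }
    else b <- b - 1
  }
  assign
}

#' Build analysis segments from matched boundaries
#'
#' Segment `i` runs from boundary `i - 1` (entry) to boundary `i` (exit); its
#' entry and exit times are the matched passage times of those boundaries.
#' Segments adjacent to an unmatched boundary are dropped.
#'
#' @param boundaries Output of [match_boundaries()].
#' @return Data frame with one row per segment: `id`, `start_chainage`,
#'   `end_chainage`, start/end coordinates, `entry_time`, `exit_time`.
#'   Empty (with a warning) when fewer than 2 boundaries are matched.
#' @export
build_segments <- function(boundaries) {
  stopifnot("matched_time" %in% names(boundaries))
  nb <- nrow(boundaries)
  empty <- data.frame(id = integer(), start_chainage = numeric(),
                      end_chainage = numeric(), start_lat = numeric(),
                      start_lon = numeric(), end_lat = numeric(),
                      end_lon = numeric(), entry_time = numeric(),
                      exit_time = numeric())
  if (sum(!is.na(boundaries$matched_time)) < 2) {
    warning("fewer than 2 matched boundaries; no segments built")
    return(empty)
  }
  rows <- lapply(seq_len(nb - 1), function(i) {
    a <- boundaries[i, ]
    b <- boundaries[i + 1, ]
    if (is.na(a$matched_time) || is.na(b$matched_time)) return(NULL)
    if (a$matched_time >= b$matched_time) return(NULL)
    data.frame(id = b$index, start_chainage = a$chainage,
               end_chainage = b$chainage,
               start_lat = a$lat, start_lon = a$lon,
               end_lat = b$lat, end_lon = b$lon,
               entry_time = a$matched_time, exit_time = b$matched_time)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no valid segments after dropping unmatched boundaries")
    return(empty)
  }
  rownames(out) <- NULL
  out
}
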