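#' Great-circle distance between coordinate pairs
#'
#' Spherical (haversine) distance on an Earth of radius 6,371,000 m, the model
#' used throughout the package for chainage, boundary matching, and GPS
#' interpolation. At city scale the difference from an ellipsoidal model is
#' below 0.5%.
#'
#' @param lat1,lon1 Numeric vectors, first point(s) in WGS84 decimal degrees.
#' @param lat2,lon2 Numeric vectors, second point(s), recycled as needed.
#' @return Numeric vector of distances in metres.
#' @examples
#' geodesic_distance(0, 0, 1, 0) # one degree of latitude, ~111.19 km
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  stopifnot(
    all(abs(lat1) <= 90), all(abs(lat2) <= 90),
    all(abs(lon1) <= 180), all(abs(lon2) <= 180)
  )
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

# Cumulative chainage (metres from route start) at each polyline vertex.
route_chainage <- function(route) {
  n <- nrow(route)
  if (n < 2) stop("route polyline needs at least 2 points")
  d <- geodesic_distance(route$lat[-n], route$lon[-n],
                         route$lat[-1], route$lon[-1])
  if (any(d == 0)) stop("route polyline has repeated consecutive points")
  c(0, cumsum(d))
}

# Locate points at given chainages along a polyline by linear interpolation
# on the great-circle edge containing each chainage.
point_at_chainage <- function(route, s) {
  cum <- route_chainage(route)
  total <- cum[length(cum)]
  if (any(s < 0 | s > total + 1e-9)) stop("chainage outside route extent")
  s <- pmin(s, total)
  # edge index for each target chainage
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(route) - 1)
  p1 <- cbind(route$lon[idx], route$lat[idx])
  p2 <- cbind(route$lon[idx + 1], route$lat[idx + 1])
  frac_m <- s - cum[idx]
  brg <- geosphere::bearing(p1, p2)
  out <- geosphere::destPoint(p1, brg, frac_m, r = EARTH_RADIUS_M)
  # exact endpoints where the chainage falls on a vertex
  on_vertex <- frac_m < 1e-9
  out[on_vertex, 1] <- p1[on_vertex, 1]
  out[on_vertex, 2] <- p1[on_vertex, 2]
  data.frame(lat = out[, 2], lon = out[, 1])
}

# n points interior to the great circle from point 1 to point 2, uniformly
# spaced along the arc (matches uniform spacing in time across a GPS gap).
gc_interpolate <- function(lat1, lon1, lat2, lon2, n) {
  pts <- geosphere::gcIntermediate(c(lon1, lat1), c(lon2, lat2),
                                   n = n, addStartEnd = FALSE)
  pts <- matrix(pts, ncol = 2)
  data.frame(lat = pts[, 2], lon = pts[, 1])
}
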