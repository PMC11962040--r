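# Spherical geometry primitives shared by the track-processing and simulation
# code. All distances are great-circle on a sphere of radius 6371 km, the
# conventional mean Earth radius in movement ecology; positional error from
# sphericity is far below GPS noise at foraging-trip scales.

.EARTH_RADIUS_KM <- 6371.0

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.check_lat_lon <- function(lat, lon) {
  if (!all(is.finite(lat)) || !all(is.finite(lon))) {
    abort("latitude/longitude must be finite")
  }
  if (any(lat < -90 | lat > 90)) abort("latitude out of [-90, 90]")
  if (any(lon < -180 | lon > 180 + 1e-9)) abort("longitude out of [-180, 180]")
  invisible(TRUE)
}

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km. Inputs are recycled, so
#' the function works both for a single pair and for aligned coordinate
#' vectors.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 1, 0) # one degree of latitude, ~111.2 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  .check_lat_lon(lat1, lon1)
  .check_lat_lon(lat2, lon2)
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1)
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * .EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial bearing from one point to another
#'
#' @inheritParams haversine_km
#' @return Bearing(s) in radians in (-pi, pi], measured clockwise from north.
#' @export
bearing_rad <- function(lat1, lon1, lat2, lon2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  atan2(y, x)
}

#' Wrap an angle to (-pi, pi]
#'
#' @param x Angle(s) in radians.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  out <- ((x + pi) %% (2 * pi)) - pi
  # map -pi to +pi so the interval is (-pi, pi]
  out[!is.na(out) & out <= -pi] <- pi
  out
}

# Advance a position by a small planar step (equirectangular approximation;
# adequate for steps up to ~10 km away from the poles, error < 0.1%).
.advance_position <- function(lat, lon, step_km, bearing) {
  dlat <- step_km * cos(bearing) / (.EARTH_RADIUS_KM * pi / 180)
  dlon <- step_km * sin(bearing) / (.EARTH_RADIUS_KM * pi / 180 * cos(.deg2rad(lat)))
  list(lat = lat + dlat, lon = lon + dlon)
}
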