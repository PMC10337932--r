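#' @title Spherical-earth navigation helpers
#' @description Great-circle distance, initial bearing and destination-point
#'   formulas on a sphere of radius 6371 km, plus conversions between compass
#'   headings and (u, v) velocity components. Longitudes are handled in the
#'   0--360 degree convention so that tracks crossing the 180 degree meridian
#'   stay continuous.
#' @name geo-utils
NULL

#' Mean Earth radius used throughout, in metres.
#' @keywords internal
EARTH_RADIUS_M <- 6371000

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalise longitudes to [0, 360)
#'
#' @param lon longitude(s) in degrees, any convention.
#' @return longitude(s) in `[0, 360)`.
#' @export
wrap_lon <- function(lon) ((lon %% 360) + 360) %% 360

#' Great-circle distance
#'
#' Haversine distance on a 6371-km sphere. Vectorised over all arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees.
#' @return distance in metres.
#' @export
gc_distance <- function(lat1, lon1, lat2, lon2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dp <- deg2rad(lat2 - lat1)
  dl <- deg2rad(wrap_lon(lon2) - wrap_lon(lon1))
  dl <- ifelse(dl > 180 * pi / 180, dl - 2 * pi, ifelse(dl < -pi, dl + 2 * pi, dl))
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing
#'
#' @inheritParams gc_distance
#' @return compass bearing in degrees `[0, 360)` (0 = north, 90 = east).
#' @export
gc_bearing <- function(lat1, lon1, lat2, lon2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dl <- deg2rad(wrap_lon(lon2) - wrap_lon(lon1))
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  (rad2deg(atan2(y, x)) + 360) %% 360
}

#' Destination point along a great circle
#'
#' @param lat,lon start point, degrees.
#' @param bearing compass azimuth, degrees.
#' @param dist_m distance travelled, metres.
#' @return list with `lat` (degrees) and `lon` (degrees, 0--360).
#' @export
gc_destination <- function(lat, lon, bearing, dist_m) {
  d <- dist_m / EARTH_RADIUS_M
  p1 <- deg2rad(lat); l1 <- deg2rad(wrap_lon(lon)); th <- deg2rad(bearing)
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(th))
  l2 <- l1 + atan2(sin(th) * sin(d) * cos(p1), cos(d) - sin(p1) * sin(p2))
  list(lat = rad2deg(p2), lon = wrap_lon(rad2deg(l2)))
}

#' Convert a compass heading and speed to (u, v) components
#'
#' u is the eastward and v the northward component, matching the wind/current
#' field convention.
#'
#' @param heading compass degrees.
#' @param speed m/s.
#' @return list with `u`, `v` in m/s.
#' @export
heading_to_uv <- function(heading, speed) {
  list(u = speed * sin(deg2rad(heading)), v = speed * cos(deg2rad(heading)))
}

#' Compass direction a vector points toward
#'
#' @param u,v eastward/northward components.
#' @return compass degrees `[0, 360)`.
#' @export
uv_to_heading <- function(u, v) (rad2deg(atan2(u, v)) + 360) %% 360

#' Displace a position by a velocity over a time step
#'
#' The displacement has magnitude `|v| * dt` and follows the great circle
#' along the velocity azimuth; longitude is wrapped to 0--360. A zero
#' velocity returns the input position exactly.
#'
#' @param lat,lon position, degrees.
#' @param u,v velocity components, m/s.
#' @param dt_hours time step, hours (> 0).
#' @return list with `lat`, `lon`.
#' @export
step_position <- function(lat, lon, u, v, dt_hours) {
  stopifnot(dt_hours > 0)
  speed <- sqrt(u^2 + v^2)
  if (speed == 0) return(list(lat = lat, lon = wrap_lon(lon)))
  gc_destination(lat, lon, uv_to_heading(u, v), speed * dt_hours * 3600)
}

#' Fold an angular difference to [0, 180]
#'
#' @param a angle difference in degrees (any sign/magnitude).
#' @return folded angle in `[0, 180]`.
#' @export
fold_angle <- function(a) {
  a <- abs(a) %% 360
  ifelse(a > 180, 360 - a, a)
}
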