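# Spherical geodesy on the authalic radius. One convention everywhere:
# bearings are compass degrees (clockwise from north), turn angles are
# radians with counterclockwise positive, distances are kilometres.

# authalic Earth radius, km
.R_EARTH_KM <- 6371.0072

#' Geodesic distance between points
#'
#' Haversine distance on a sphere of authalic radius (6371.0072 km), the
#' convention used throughout the package for both ~km and ~100 km scales.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees; vectors recycle.
#' @return Distance(s) in kilometres.
#' @export
gc_distance_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .R_EARTH_KM * 1000) / 1000
}

#' Initial bearing from one point to another
#'
#' @inheritParams gc_distance_km
#' @return Compass bearing in degrees (clockwise from north), in [0, 360).
#' @export
gc_bearing <- function(lon1, lat1, lon2, lat2) {
  b <- geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2), f = 0)
  b %% 360
}

# bearing of the displacement p1 -> p2 evaluated AT p2 (the great circle's
# forward direction where it arrives); needed so a straight geodesic has
# zero turn angle at every interior fix
gc_final_bearing <- function(lon1, lat1, lon2, lat2) {
  (gc_bearing(lon2, lat2, lon1, lat1) + 180) %% 360
}

#' Destination point from bearing and distance
#'
#' @inheritParams gc_distance_km
#' @param lon,lat Start point, decimal degrees.
#' @param bearing_deg Compass bearing in degrees.
#' @param dist_km Geodesic distance in kilometres.
#' @return A two-column matrix of lon, lat.
#' @export
gc_destination <- function(lon, lat, bearing_deg, dist_km) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing_deg, dist_km * 1000,
                            a = .R_EARTH_KM * 1000, f = 0)
  p[, 1] <- ((p[, 1] + 180) %% 360) - 180
  colnames(p) <- c("lon", "lat")
  p
}

# wrap radians to (-pi, pi]
wrap_pi <- function(x) {
  r <- ((x + pi) %% (2 * pi)) - pi
  r[r <= -pi + 1e-15] <- pi
  r
}

# turn angle at a vertex: counterclockwise positive, so a clockwise (right)
# turn is negative. bearing_in is the incoming displacement's bearing at the
# vertex, bearing_out the outgoing displacement's initial bearing.
turn_angle_rad <- function(bearing_in, bearing_out) {
  wrap_pi((bearing_in - bearing_out) * pi / 180)
}

# apply a turn to a heading: new compass bearing after turning by theta
# (counterclockwise positive)
apply_turn <- function(heading_deg, turn_rad) {
  (heading_deg - turn_rad * 180 / pi) %% 360
}
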