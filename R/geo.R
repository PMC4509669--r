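# Geodesy helpers. Filter distances use the haversine on a spherical Earth
# (R = 6371 km); the state-space model works on a local tangent plane, which
# at the <100 km scales involved introduces negligible distortion.

EARTH_RADIUS_KM <- 6371

#' Great-circle distance (km)
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorised).
#' @return distances in kilometres.
#' @export
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

# Equirectangular projection about (lon0, lat0); returns km east/north.
.project_km <- function(lon, lat, lon0, lat0) {
  kpd <- pi / 180 * EARTH_RADIUS_KM
  cbind(x = (lon - lon0) * cos(lat0 * pi / 180) * kpd,
        y = (lat - lat0) * kpd)
}

.unproject_km <- function(x, y, lon0, lat0) {
  kpd <- pi / 180 * EARTH_RADIUS_KM
  cbind(lon = lon0 + x / (cos(lat0 * pi / 180) * kpd),
        lat = lat0 + y / kpd)
}

# Interior angle (degrees, in [0, 180]) at vertex B of the path A-B-C.
# 0 means C lies back along BA (a full-reversal spike); 180 means straight
# through.
.interior_angle <- function(lonA, latA, lonB, latB, lonC, latC) {
  b1 <- geosphere::bearing(cbind(lonB, latB), cbind(lonA, latA))
  b2 <- geosphere::bearing(cbind(lonB, latB), cbind(lonC, latC))
  abs(((b2 - b1 + 180) %% 360) - 180)
}
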