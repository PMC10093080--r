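# Local azimuthal-equidistant tangent plane at the hive: x east, y north,
# meters. Bearings and great-circle distances from the hive are preserved
# exactly; distortion elsewhere is negligible at foraging ranges (<= 10 km).

to_tangent <- function(site, lat_deg, lon_deg) {
  assert_hive_site(site)
  n <- length(lat_deg)
  if (n == 0L) return(tibble(x = numeric(), y = numeric()))
  hive <- c(site$lon_deg, site$lat_deg)
  pts <- cbind(lon_deg, lat_deg)
  d <- geosphere::distHaversine(hive, pts, r = EARTH_RADIUS_M)
  # spherical initial bearing (exact inverse of the spherical destination)
  phi1 <- deg2rad(site$lat_deg); phi2 <- deg2rad(lat_deg)
  dlam <- deg2rad(lon_deg - site$lon_deg)
  b <- rad2deg(atan2(sin(dlam) * cos(phi2),
                     cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)))
  b[d == 0] <- 0
  tibble(x = d * sin(deg2rad(b)), y = d * cos(deg2rad(b)))
}

from_tangent <- function(site, x, y) {
  assert_hive_site(site)
  d <- sqrt(x^2 + y^2)
  b <- wrap_degrees(rad2deg(atan2(x, y)))
  ll <- geosphere::destPoint(c(site$lon_deg, site$lat_deg), b = b, d = d,
                             r = EARTH_RADIUS_M)
  lat <- unname(ll[, "lat"]); lon <- unname(ll[, "lon"])
  lat[d == 0] <- site$lat_deg
  lon[d == 0] <- site$lon_deg
  tibble(lat_deg = lat, lon_deg = lon)
}

tangent_dist <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)
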