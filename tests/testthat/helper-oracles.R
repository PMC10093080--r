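# Independent oracles, implemented separately from the package's own routes.

# Michalsky (1988) low-precision solar ephemeris (Astronomical Almanac
# formulation: mean longitude/anomaly -> ecliptic longitude -> RA/dec,
# sidereal time -> hour angle). Independent of the package's NOAA route
# (declination via apparent longitude + equation of time).
oracle_solar <- function(ts, lat, lon) {
  t <- as.numeric(ts)
  jd <- t / 86400 + 2440587.5
  delta <- jd - 2451545
  rad <- pi / 180
  mnlong <- (280.460 + 0.9856474 * delta) %% 360
  mnanom <- ((357.528 + 0.9856003 * delta) %% 360) * rad
  eclong <- ((mnlong + 1.915 * sin(mnanom) + 0.020 * sin(2 * mnanom)) %% 360) * rad
  oblqec <- (23.439 - 0.0000004 * delta) * rad
  ra <- atan2(cos(oblqec) * sin(eclong), cos(eclong))
  dec <- asin(sin(oblqec) * sin(eclong))
  hour <- (t %% 86400) / 3600
  gmst <- (6.697375 + 0.0657098242 * delta + hour) %% 24
  lmst <- ((gmst + lon / 15) %% 24) * 15 * rad
  ha <- lmst - ra
  phi <- lat * rad
  el <- asin(sin(dec) * sin(phi) + cos(dec) * cos(phi) * cos(ha))
  az <- atan2(sin(ha), cos(ha) * sin(phi) - tan(dec) * cos(phi))
  list(azimuth_deg = (az / rad + 180) %% 360, elevation_deg = el / rad)
}

# Closed-form spherical destination point (hand-written; the package goes
# through geosphere).
oracle_destination <- function(lat, lon, bearing, dist, R = 6371000) {
  rad <- pi / 180
  phi1 <- lat * rad; lam1 <- lon * rad; th <- bearing * rad; dr <- dist / R
  phi2 <- asin(sin(phi1) * cos(dr) + cos(phi1) * sin(dr) * cos(th))
  lam2 <- lam1 + atan2(sin(th) * sin(dr) * cos(phi1),
                       cos(dr) - sin(phi1) * sin(phi2))
  c(lat = phi2 / rad, lon = ((lam2 / rad + 180) %% 360) - 180)
}

# Brute-force minimal enclosing circle over all point pairs and triples.
oracle_mec <- function(x, y, tol = 1e-7) {
  n <- length(x)
  if (n == 1L) return(list(x = x, y = y, r = 0))
  covers <- function(cx, cy, r) all(sqrt((x - cx)^2 + (y - cy)^2) <= r * (1 + tol) + 1e-12)
  best <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cx <- (x[i] + x[j]) / 2; cy <- (y[i] + y[j]) / 2
    r <- sqrt((x[i] - cx)^2 + (y[i] - cy)^2)
    if (covers(cx, cy, r) && (is.null(best) || r < best$r))
      best <- list(x = cx, y = cy, r = r)
  }
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    d <- 2 * (x[i] * (y[j] - y[k]) + x[j] * (y[k] - y[i]) + x[k] * (y[i] - y[j]))
    if (abs(d) < 1e-12) next
    ux <- ((x[i]^2 + y[i]^2) * (y[j] - y[k]) + (x[j]^2 + y[j]^2) * (y[k] - y[i]) +
             (x[k]^2 + y[k]^2) * (y[i] - y[j])) / d
    uy <- ((x[i]^2 + y[i]^2) * (x[k] - x[j]) + (x[j]^2 + y[j]^2) * (x[i] - x[k]) +
             (x[k]^2 + y[k]^2) * (x[j] - x[i])) / d
    r <- sqrt((x[i] - ux)^2 + (y[i] - uy)^2)
    if (covers(ux, uy, r) && (is.null(best) || r < best$r))
      best <- list(x = ux, y = uy, r = r)
  }
  best
}

# Brute-force smallest covering arc: every arc that starts (clockwise) at
# one observed bearing and ends at another is a candidate.
oracle_sector <- function(bearings, coverage) {
  b <- sort(bearings %% 360)
  n <- length(b)
  need <- ceiling(coverage * n)
  if (need <= 1L) return(0)
  best <- 360
  for (i in seq_len(n)) for (j in seq_len(n)) {
    w <- (b[j] - b[i]) %% 360
    inside <- sum(((b - b[i]) %% 360) <= w + 1e-9)
    if (inside >= need && w < best) best <- w
  }
  best
}
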