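EARTH_RADIUS_M <- 6371000

#' Compass bearing encoded by a dance angle
#'
#' On the vertical comb "up" stands for the sun's azimuth, so the ground
#' bearing of the advertised resource is the solar azimuth plus the dance
#' angle from vertical (both clockwise positive), wrapped to \[0, 360).
#'
#' @param angle_deg dance angle from vertical in degrees, clockwise positive.
#' @param solar_azimuth_deg solar azimuth in degrees clockwise from true north.
#' @return bearing in degrees, \[0, 360). Vectorized.
#' @export
#' @examples
#' bearing_from_dance(0, 137)    # dance straight up points at the sun: 137
#' bearing_from_dance(350, 20)   # 10
bearing_from_dance <- function(angle_deg, solar_azimuth_deg) {
  if (any(!is.finite(angle_deg)) || any(!is.finite(solar_azimuth_deg)))
    abort_invalid("angle_deg and solar_azimuth_deg must be finite")
  wrap_degrees(solar_azimuth_deg + angle_deg)
}

#' Distance calibration model
#'
#' The waggle duration encodes distance linearly: `distance = v * duration`,
#' with `v` (m/s) estimated at the site against a feeder at known range.
#' `v_rounded` is `v` rounded to the nearest 10 m/s, mirroring the
#' field convention of quoting the factor as an "about" figure.
#'
#' @param v calibration factor in meters per second of waggling (> 0).
#' @param estimator label of the duration summary the factor was derived
#'   from (`"median"`, `"mean"`, or `"external"` for a supplied value).
#' @param n number of durations used in the estimate.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(v, estimator = "external", n = NA_integer_) {
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
    abort_invalid("calibration factor v must be a single positive number")
  structure(list(v = as.numeric(v), v_rounded = round(v / 10) * 10,
                 estimator = estimator, n = as.integer(n)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> v = %.2f m/s (about %g m/s), %s of n = %s\n",
              x$v, x$v_rounded, x$estimator,
              ifelse(is.na(x$n), "?", x$n)))
  invisible(x)
}

#' Estimate the distance calibration factor from feeder dances
#'
#' With foragers recruited to a feeder at known range, the calibration
#' factor is the known distance divided by a robust summary (default:
#' median) of the observed waggle durations.
#'
#' @param durations_s waggle durations in seconds (nonempty, positive summary).
#' @param known_distance_m true hive-to-feeder distance in meters (> 0).
#' @param estimator `"median"` (default) or `"mean"`.
#' @return a [calibration_model()].
#' @export
#' @examples
#' calibrate(c(0.5, 0.6, 0.7), 300)  # v = 500 m/s
calibrate <- function(durations_s, known_distance_m,
                      estimator = c("median", "mean")) {
  estimator <- match.arg(estimator)
  if (length(durations_s) == 0L || any(is.na(durations_s)))
    abort_invalid("durations_s must be nonempty with no NAs")
  if (!is.numeric(known_distance_m) || length(known_distance_m) != 1L ||
      is.na(known_distance_m) || known_distance_m <= 0)
    abort_invalid("known_distance_m must be a single positive number")
  est <- switch(estimator, median = stats::median(durations_s),
                mean = mean(durations_s))
  if (est <= 0)
    abort_invalid("duration summary is not positive; cannot calibrate")
  calibration_model(known_distance_m / est, estimator = estimator,
                    n = length(durations_s))
}

#' Foraging distance from waggle duration
#'
#' @param duration_s waggle duration(s) in seconds (>= 0).
#' @param calibration a [calibration_model()].
#' @return distance in meters, vectorized.
#' @export
#' @examples
#' distance_from_duration(0.60, calibration_model(383.33))  # ~230 m
distance_from_duration <- function(duration_s, calibration) {
  if (!inherits(calibration, "calibration_model"))
    abort_invalid("`calibration` must be a calibration_model")
  if (any(is.na(duration_s)) || any(duration_s < 0))
    abort_invalid("duration_s must be non-negative")
  calibration$v * duration_s
}

#' Project a vector endpoint from the hive
#'
#' Great-circle destination on a sphere of radius 6,371 km from the hive
#' along an initial bearing; distance 0 returns the hive coordinates
#' exactly. Ellipsoidal corrections are negligible at foraging ranges
#' (<= 10 km).
#'
#' @param site a [hive_site()].
#' @param bearing_deg initial bearing(s), degrees clockwise from true north.
#' @param distance_m ground distance(s) in meters (>= 0).
#' @param source_id optional label(s) recording which phase/dance produced
#'   each endpoint.
#' @param kind `"phase"` or `"dance"` provenance label.
#' @return a tibble of class `geo_endpoints` with columns `source_id`,
#'   `kind`, `lat_deg`, `lon_deg`, `bearing_deg`, `distance_m`.
#' @export
project_endpoint <- function(site, bearing_deg, distance_m,
                             source_id = NA_character_, kind = "phase") {
  assert_hive_site(site)
  if (any(is.na(distance_m)) || any(distance_m < 0))
    abort_invalid("distance_m must be non-negative")
  n <- max(length(bearing_deg), length(distance_m))
  bearing_deg <- wrap_degrees(rep_len(bearing_deg, n))
  distance_m <- rep_len(distance_m, n)
  ll <- geosphere::destPoint(c(site$lon_deg, site$lat_deg),
                             b = bearing_deg, d = distance_m,
                             r = EARTH_RADIUS_M)
  lat <- ll[, "lat"]
  lon <- ll[, "lon"]
  # destination at distance 0 must be the hive itself, bit-exactly
  lat[distance_m == 0] <- site$lat_deg
  lon[distance_m == 0] <- site$lon_deg
  out <- tibble(source_id = rep_len(as.character(source_id), n),
                kind = rep_len(kind, n),
                lat_deg = unname(lat), lon_deg = unname(lon),
                bearing_deg = bearing_deg, distance_m = distance_m)
  class(out) <- unique(c("geo_endpoints", class(out)))
  out
}

#' Per-waggle ground accuracy
#'
#' A forager cannot signal duration more finely than one waggle cycle, so
#' the ground resolution of the distance code is the calibration factor
#' divided by the waggle oscillation frequency.
#'
#' @param calibration a [calibration_model()] or a bare factor in m/s.
#' @param waggle_freq_hz waggle oscillation frequency in Hz (> 0).
#' @return list with `accuracy_m` (m per waggle cycle) and
#'   `accuracy_m_rounded` (nearest meter).
#' @export
#' @examples
#' waggle_accuracy(380, 13)  # 29.23 m, rounded 29
waggle_accuracy <- function(calibration, waggle_freq_hz) {
  v <- calibration_v(calibration)
  if (!is.numeric(waggle_freq_hz) || length(waggle_freq_hz) != 1L ||
      is.na(waggle_freq_hz) || waggle_freq_hz <= 0)
    abort_invalid("waggle_freq_hz must be a single positive number")
  acc <- v / waggle_freq_hz
  list(accuracy_m = acc, accuracy_m_rounded = as.integer(round(acc)))
}

#' Ground-distance quantum of frame-timed durations
#'
#' Durations measured in whole video frames are multiples of `1/fps`, so
#' decoded distances are multiples of `v/fps`: endpoints fall on concentric
#' rings this many meters apart.
#'
#' @inheritParams waggle_accuracy
#' @param fps video acquisition rate in frames per second (> 0).
#' @return list with `spacing_m` and `spacing_m_rounded` (nearest meter).
#' @export
#' @examples
#' ring_spacing(380, 60)  # 6.33 m, rounded 6
ring_spacing <- function(calibration, fps) {
  v <- calibration_v(calibration)
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0)
    abort_invalid("fps must be a single positive number")
  sp <- v / fps
  list(spacing_m = sp, spacing_m_rounded = as.integer(round(sp)))
}

calibration_v <- function(calibration) {
  if (inherits(calibration, "calibration_model")) return(calibration$v)
  if (is.numeric(calibration) && length(calibration) == 1L &&
      !is.na(calibration) && calibration > 0) return(as.numeric(calibration))
  abort_invalid("calibration must be a calibration_model or a positive number")
}

#' Nyquist sampling margin for the waggle oscillation
#'
#' Ratio of the video frame rate to twice the highest signal frequency of
#' interest; the waggle oscillation is adequately sampled iff the ratio is
#' at least 1.
#'
#' @param fps video acquisition rate in frames per second (> 0).
#' @param max_signal_hz highest waggle oscillation frequency to resolve (> 0).
#' @return list with `ratio` and `adequate` (`ratio >= 1`).
#' @export
#' @examples
#' nyquist_margin(60, 18)  # 1.67, adequate
nyquist_margin <- function(fps, max_signal_hz) {
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0 ||
      !is.numeric(max_signal_hz) || length(max_signal_hz) != 1L ||
      is.na(max_signal_hz) || max_signal_hz <= 0)
    abort_invalid("fps and max_signal_hz must be single positive numbers")
  r <- fps / (2 * max_signal_hz)
  list(ratio = r, adequate = r >= 1)
}

#' Width of the smallest arc covering a fraction of bearings
#'
#' Summarizes the angular spread of endpoint bearings as the width of the
#' narrowest circular arc containing at least `coverage_fraction` of them,
#' found by exhaustive search over arcs anchored (starting clockwise) at
#' each observed bearing. Ties are broken toward the earliest anchor
#' bearing, making the result deterministic.
#'
#' @param bearings_deg bearings in degrees (nonempty).
#' @param coverage_fraction fraction of bearings the arc must contain,
#'   in (0, 1]. Default 0.95 (roughly +/- 2 sd of the angular scatter).
#' @return arc width in degrees, \[0, 360).
#' @export
#' @examples
#' sector_width(c(0, 10, 20, 350), 1.0)  # 30: arc 350 -> 20
sector_width <- function(bearings_deg, coverage_fraction = 0.95) {
  if (length(bearings_deg) == 0L || any(is.na(bearings_deg)))
    abort_invalid("bearings_deg must be nonempty with no NAs")
  if (!is.numeric(coverage_fraction) || length(coverage_fraction) != 1L ||
      is.na(coverage_fraction) || coverage_fraction <= 0 ||
      coverage_fraction > 1)
    abort_invalid("coverage_fraction must be in (0, 1]")
  b <- sort(wrap_degrees(bearings_deg))
  n <- length(b)
  m <- ceiling(coverage_fraction * n)
  if (m <= 1L) return(0)
  ext <- c(b, b + 360)
  widths <- ext[seq_len(n) + (m - 1L)] - b
  # min() takes the first minimum -> earliest anchor bearing wins ties
  min(widths)
}

#' Geocode waggle phases or dances to vector endpoints
#'
#' The full dance-to-ground transform: for each record, the solar azimuth
#' at its own timestamp is added to its angle from vertical to give a
#' compass bearing, the frame-timed duration is scaled by the calibration
#' factor to give a distance, and the endpoint is projected from the hive
#' along that bearing. Phase-level endpoints use each phase's own angle and
#' duration; dance-level endpoints use the dance's circular-mean angle and
#' its duration summary (default: median).
#'
#' A warning (not an error) is raised if any record's timestamp falls when
#' the sun is below the horizon, since a dance decoded outside daylight
#' almost certainly carries a timestamp error.
#'
#' @param phases a `waggle_phases` table.
#' @param dances a `dances` table from [phases_to_dances()].
#' @param site a [hive_site()].
#' @param calibration a [calibration_model()].
#' @param duration_estimator which dance duration summary encodes distance:
#'   `"median"` (default) or `"mean"`.
#' @return a `geo_endpoints` tibble (see [project_endpoint()]); `kind` is
#'   `"phase"` or `"dance"`, `source_id` is `dance_id` or
#'   `dance_id#phase_index`.
#' @export
geocode_phases <- function(phases, site, calibration) {
  phases <- validate_phases(as_tibble(phases))
  assert_hive_site(site)
  if (nrow(phases) == 0L)
    return(project_endpoint(site, numeric(), numeric(), character()))
  sol <- solar_position(phases$timestamp_utc, site$lat_deg, site$lon_deg)
  warn_if_dark(sol)
  bearing <- bearing_from_dance(phases$angle_deg, sol$azimuth_deg)
  dur <- duration_from_frames(phases$frame_start, phases$frame_end, site$fps)
  dist <- distance_from_duration(dur, calibration)
  project_endpoint(site, bearing, dist,
                   source_id = paste(phases$dance_id, phases$phase_index,
                                     sep = "#"),
                   kind = "phase")
}

#' @rdname geocode_phases
#' @export
geocode_dances <- function(dances, site, calibration,
                           duration_estimator = c("median", "mean")) {
  duration_estimator <- match.arg(duration_estimator)
  assert_hive_site(site)
  dances <- as_tibble(dances)
  if (nrow(dances) == 0L)
    return(project_endpoint(site, numeric(), numeric(), character(),
                            kind = "dance"))
  if (any(!dances$mean_defined))
    abort_invalid(sprintf(
      "circular mean undefined for dance(s): %s",
      paste(dances$dance_id[!dances$mean_defined], collapse = ", ")))
  sol <- solar_position(dances$timestamp_utc, site$lat_deg, site$lon_deg)
  warn_if_dark(sol)
  bearing <- bearing_from_dance(dances$mean_angle_deg, sol$azimuth_deg)
  dur <- switch(duration_estimator, median = dances$duration_median_s,
                mean = dances$duration_mean_s)
  dist <- distance_from_duration(dur, calibration)
  project_endpoint(site, bearing, dist, source_id = dances$dance_id,
                   kind = "dance")
}

warn_if_dark <- function(sol) {
  dark <- !check_daylight(sol)
  if (any(dark))
    warning(sprintf("%d record(s) timestamped with the sun below the horizon",
                    sum(dark)), call. = FALSE)
  invisible(NULL)
}
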