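#' Configuration for a synthetic dance session
#'
#' Defines the conditions of a feeder experiment: a colony recruiting to a
#' single feeder at known bearing and distance, decoded into frame-timed
#' waggle phases with realistic angular scatter, duration noise and frame
#' quantization. The defaults emulate a 10-minute midsummer feeder session
#' at a mid-latitude western-European site: feeder 230 m due east, true
#' calibration factor 380 m/s, 141 dances of 8-14 phases each, duration sd
#' 0.14 s quantized to 1/60 s, angular sd 13.5 deg (so roughly 95% of
#' phases fall in a 54 deg sector), waggle frequency N(12.67, 1.89^2) Hz.
#'
#' @param feeder_bearing_deg true hive-to-feeder bearing, degrees from north.
#' @param feeder_distance_m true hive-to-feeder distance, meters.
#' @param v_true true duration-to-distance factor, m/s.
#' @param n_dances number of dances to simulate (>= 1).
#' @param phases_per_dance integer `c(min, max)`; per-dance phase counts are
#'   drawn uniformly from this range.
#' @param duration_sd_s per-phase duration noise sd, seconds.
#' @param angle_sd_deg per-phase angular noise sd (wrapped normal), degrees.
#' @param waggle_freq_mean_hz,waggle_freq_sd_hz waggle oscillation frequency
#'   distribution (per dance), Hz.
#' @param fps video frame rate used for quantization, frames/s.
#' @param site a [hive_site()].
#' @param session_start_utc session start instant (UTC).
#' @param session_len_min session length, minutes.
#' @param seed integer RNG seed; everything downstream is reproducible from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(feeder_bearing_deg = 90, feeder_distance_m = 230,
                       v_true = 380, n_dances = 141,
                       phases_per_dance = c(8, 14),
                       duration_sd_s = 0.14, angle_sd_deg = 13.5,
                       waggle_freq_mean_hz = 12.67, waggle_freq_sd_hz = 1.89,
                       fps = 60,
                       site = hive_site(46.15, -0.64, fps = 60,
                                        utc_offset_h = 2),
                       session_start_utc = "2022-06-21T10:49:00Z",
                       session_len_min = 10, seed = 1L) {
  assert_hive_site(site)
  if (n_dances < 1) abort_config("n_dances must be >= 1")
  if (length(phases_per_dance) != 2L || any(phases_per_dance < 1) ||
      phases_per_dance[2] < phases_per_dance[1])
    abort_config("phases_per_dance must be c(min, max) with 1 <= min <= max")
  for (v in list(feeder_distance_m, v_true, fps, session_len_min))
    if (!is.numeric(v) || v <= 0) abort_config("scales must be positive")
  if (duration_sd_s < 0 || angle_sd_deg < 0 || waggle_freq_sd_hz < 0)
    abort_config("noise sds must be non-negative")
  if (waggle_freq_mean_hz <= 0) abort_config("waggle_freq_mean_hz must be positive")
  start <- parse_utc(session_start_utc)
  if (is.na(start)) abort_config("unparsable session_start_utc")
  # a duration model that truncates at the frame quantum more often than
  # not is mis-specified, not noisy
  if (duration_sd_s > 0 &&
      pnorm(1 / fps, mean = feeder_distance_m / v_true,
            sd = duration_sd_s) > 0.5)
    abort_config("duration_sd_s so large that > 50% of durations would truncate at 1/fps")
  structure(
    list(feeder_bearing_deg = wrap_degrees(feeder_bearing_deg),
         feeder_distance_m = feeder_distance_m, v_true = v_true,
         n_dances = as.integer(n_dances),
         phases_per_dance = as.integer(phases_per_dance),
         duration_sd_s = duration_sd_s, angle_sd_deg = angle_sd_deg,
         waggle_freq_mean_hz = waggle_freq_mean_hz,
         waggle_freq_sd_hz = waggle_freq_sd_hz, fps = fps, site = site,
         session_start_utc = start, session_len_min = session_len_min,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a waggle-phase decoding session with known ground truth
#'
#' For each dance, a timestamp is drawn uniformly over the session (whole
#' seconds); the true dance angle is the feeder bearing minus the solar
#' azimuth at that instant. Each phase perturbs that angle with wrapped
#' normal noise and draws a duration `feeder_distance/v_true +
#' N(0, duration_sd)`, truncated below at one frame; the duration is then
#' quantized to whole frames and re-derived from the frame count, exactly
#' as a human decoder reading start/end frames would produce it. Phase
#' frame indices advance within the dance with short inter-phase (return
#' run) gaps.
#'
#' @param config a [sim_config()].
#' @return list with `phases` (a `waggle_phases` tibble) and `truth`
#'   (feeder location, per-dance table of true angles/azimuths, config).
#' @export
#' @examples
#' sim <- simulate_session(sim_config(n_dances = 5, seed = 42))
#' nrow(sim$phases)
simulate_session <- function(config) {
  if (!inherits(config, "sim_config")) abort_config("not a sim_config")
  set.seed(config$seed)
  cg <- config
  site <- cg$site

  t0 <- as.numeric(cg$session_start_utc)
  dance_ts <- .POSIXct(t0 + floor(runif(cg$n_dances, 0, cg$session_len_min * 60)),
                       tz = "UTC")
  ord <- order(dance_ts)
  dance_ts <- dance_ts[ord]
  sol <- solar_position(dance_ts, site$lat_deg, site$lon_deg)
  true_angle <- wrap_degrees(cg$feeder_bearing_deg - sol$azimuth_deg)
  ph_range <- seq.int(cg$phases_per_dance[1], cg$phases_per_dance[2])
  n_ph <- if (length(ph_range) == 1L) rep(ph_range, cg$n_dances)
          else sample(ph_range, cg$n_dances, replace = TRUE)
  freq <- rnorm(cg$n_dances, cg$waggle_freq_mean_hz, cg$waggle_freq_sd_hz)

  rows <- vector("list", cg$n_dances)
  for (d in seq_len(cg$n_dances)) {
    k <- n_ph[d]
    ang <- wrap_degrees(true_angle[d] + rnorm(k, 0, cg$angle_sd_deg))
    dur <- cg$feeder_distance_m / cg$v_true + rnorm(k, 0, cg$duration_sd_s)
    dur <- pmax(dur, 1 / cg$fps)
    frames <- pmax(1L, as.integer(round(dur * cg$fps)))
    gaps <- as.integer(round(cg$fps * runif(k, 0.5, 2)))
    base <- as.integer(round((as.numeric(dance_ts[d]) - t0) * cg$fps))
    starts <- base + cumsum(c(0L, (frames + gaps)[-k]))
    rows[[d]] <- tibble(
      dance_id = sprintf("d%03d", d),
      phase_index = seq_len(k) - 1L,
      frame_start = starts,
      frame_end = starts + frames,
      angle_deg = ang,
      timestamp_utc = .POSIXct(t0 + round((starts - base) / cg$fps) +
                                 (as.numeric(dance_ts[d]) - t0), tz = "UTC")
    )
  }
  phases <- validate_phases(dplyr::bind_rows(rows))

  feeder <- project_endpoint(site, cg$feeder_bearing_deg,
                             cg$feeder_distance_m, source_id = "feeder",
                             kind = "dance")
  truth <- list(
    feeder_bearing_deg = cg$feeder_bearing_deg,
    feeder_distance_m = cg$feeder_distance_m,
    feeder_lat_deg = feeder$lat_deg, feeder_lon_deg = feeder$lon_deg,
    v_true = cg$v_true,
    waggle_freq_mean_hz_drawn = mean(freq),
    dances = tibble(dance_id = sprintf("d%03d", seq_len(cg$n_dances)),
                    timestamp_utc = dance_ts,
                    solar_azimuth_deg = sol$azimuth_deg,
                    true_angle_deg = true_angle,
                    n_phases = n_ph,
                    waggle_freq_hz = freq),
    config = cg
  )
  list(phases = phases, truth = truth)
}

#' Write a simulated session to disk
#'
#' The phase table goes to the standard phase CSV; the ground truth
#' (feeder location, true calibration factor, per-dance truth and the full
#' config) to a JSON sidecar.
#'
#' @param sim result of [simulate_session()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the two paths written.
#' @export
write_session <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  phases_path <- file.path(dir, "phases.csv")
  truth_path <- file.path(dir, "truth.json")
  write_phases(sim$phases, phases_path)
  tr <- sim$truth
  tr$dances$timestamp_utc <- format_utc(tr$dances$timestamp_utc)
  tr$config$session_start_utc <- format_utc(tr$config$session_start_utc)
  tr$config$site <- unclass(tr$config$site)
  tr$config <- unclass(tr$config)
  jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(phases = phases_path, truth = truth_path))
}
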