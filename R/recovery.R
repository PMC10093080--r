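#' End-to-end recovery diagnostics against a known feeder
#'
#' Runs the full decoding pipeline on a phase table for which the feeder
#' position is known (typically from [simulate_session()]) and reports how
#' well the pipeline recovers it: calibration error, bearing and distance
#' errors of the dance-level endpoints, the heat-map peak's ground distance
#' to the feeder, the angular sector width of the phase bearings, and the
#' enclosing-circle diameter.
#'
#' @param phases a `waggle_phases` table.
#' @param site a [hive_site()].
#' @param feeder list with `bearing_deg` and `distance_m` of the true feeder.
#' @param calibration_mode `"self"` (calibrate the factor from these dances
#'   against the known feeder distance, as done in the field) or `"known"`
#'   (use `v_true` directly, isolating angular errors from calibration).
#' @param v_true true factor in m/s, required when `calibration_mode = "known"`.
#' @param bandwidth_m,cell_size_m heat-map parameters (see [density_map()]).
#' @param coverage_fraction sector coverage (see [sector_width()]).
#' @param trim_fraction see [search_area()].
#' @param map build the density map and peak-error summaries? Setting
#'   `FALSE` skips the grid (useful in many-replicate sweeps where only
#'   calibration and bearing errors are of interest).
#' @return list of named diagnostics (see Details in the fields themselves):
#'   `v_estimated`, `v_error_fraction`, `median_abs_bearing_error_deg`,
#'   `median_distance_error_m`, `peak_to_feeder_m`, `sector_width_deg`,
#'   `enclosing_diameter_m`, `n_dances`, `n_phases`.
#' @export
recovery_report <- function(phases, site, feeder,
                            calibration_mode = c("self", "known"),
                            v_true = NULL, bandwidth_m = 29, cell_size_m = 5,
                            coverage_fraction = 0.95, trim_fraction = 0,
                            map = TRUE) {
  calibration_mode <- match.arg(calibration_mode)
  assert_hive_site(site)
  dances <- phases_to_dances(phases, site$fps)
  cal <- switch(calibration_mode,
    self = calibrate(dances$duration_median_s, feeder$distance_m),
    known = {
      if (is.null(v_true)) abort_config("v_true required when calibration_mode = 'known'")
      calibration_model(v_true)
    })
  ep_ph <- geocode_phases(phases, site, cal)
  ep_dn <- geocode_dances(dances, site, cal)

  bearing_err <- angle_diff_deg(ep_dn$bearing_deg, feeder$bearing_deg)
  dist_err <- ep_dn$distance_m - feeder$distance_m

  out <- list(
    calibration_mode = calibration_mode,
    v_estimated = cal$v,
    v_error_fraction = if (!is.null(v_true)) cal$v / v_true - 1 else NA_real_,
    median_abs_bearing_error_deg = stats::median(abs(bearing_err)),
    median_distance_error_m = stats::median(dist_err),
    sector_width_deg = sector_width(ep_ph$bearing_deg, coverage_fraction),
    n_dances = nrow(dances),
    n_phases = nrow(phases)
  )
  if (map) {
    grid <- density_map(ep_dn, site, bandwidth_m = bandwidth_m,
                        cell_size_m = cell_size_m)
    sa <- search_area(grid, ep_dn, trim_fraction = trim_fraction)
    feeder_pt <- project_endpoint(site, feeder$bearing_deg, feeder$distance_m)
    ft <- to_tangent(site, feeder_pt$lat_deg, feeder_pt$lon_deg)
    pt <- to_tangent(site, sa$peak_lat_deg, sa$peak_lon_deg)
    out$peak_to_feeder_m <- tangent_dist(ft$x, ft$y, pt$x, pt$y)
    out$enclosing_diameter_m <- sa$diameter_m
  }
  out
}
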