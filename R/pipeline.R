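#' Pipeline run configuration
#'
#' Bundles the site, exactly one calibration source (an explicit factor
#' `v`, or a feeder distance to self-calibrate against), and the mapping
#' and diagnostic parameters for [run_pipeline()].
#'
#' @param site a [hive_site()].
#' @param v explicit calibration factor in m/s, or `NULL`.
#' @param feeder_distance_m known feeder distance in m for self-calibration,
#'   or `NULL`. Exactly one of `v` / `feeder_distance_m` must be given.
#' @param estimator duration summary for self-calibration and dance
#'   geocoding: `"median"` (default) or `"mean"`.
#' @param bandwidth_m,cell_size_m heat-map parameters ([density_map()]).
#' @param trim_fraction enclosing-circle trimming ([search_area()]).
#' @param coverage_fraction sector coverage ([sector_width()]).
#' @param waggle_freq_hz waggle oscillation frequency for the accuracy
#'   diagnostic, Hz. Default 13.
#' @param max_signal_hz highest frequency the video must resolve, Hz.
#'   Default 18.
#' @param session_len_min observation length in minutes for the dance-rate
#'   statistic; if `NULL`, the span of the phase timestamps is used.
#' @return an object of class `run_config`.
#' @export
run_config <- function(site, v = NULL, feeder_distance_m = NULL,
                       estimator = c("median", "mean"), bandwidth_m = 29,
                       cell_size_m = 5, trim_fraction = 0,
                       coverage_fraction = 0.95, waggle_freq_hz = 13,
                       max_signal_hz = 18, session_len_min = NULL) {
  assert_hive_site(site)
  estimator <- match.arg(estimator)
  if (is.null(v) == is.null(feeder_distance_m))
    abort_config("specify exactly one of `v` or `feeder_distance_m`")
  if (!is.null(v) && (!is.numeric(v) || v <= 0))
    abort_config("v must be positive")
  if (!is.null(feeder_distance_m) &&
      (!is.numeric(feeder_distance_m) || feeder_distance_m <= 0))
    abort_config("feeder_distance_m must be positive")
  structure(
    list(site = site, v = v, feeder_distance_m = feeder_distance_m,
         estimator = estimator, bandwidth_m = bandwidth_m,
         cell_size_m = cell_size_m, trim_fraction = trim_fraction,
         coverage_fraction = coverage_fraction,
         waggle_freq_hz = waggle_freq_hz, max_signal_hz = max_signal_hz,
         session_len_min = session_len_min),
    class = "run_config"
  )
}

#' Sampling and accuracy diagnostics
#'
#' The three numbers that say whether a recording setup can support the
#' decoding: the quantization ring spacing `v/fps`, the one-waggle ground
#' accuracy `v/f_waggle`, and the Nyquist margin `fps/(2 f_max)`. Sampling
#' is sufficient when the ring spacing does not exceed the waggle accuracy
#' (the frame clock is then not the limiting resolution).
#'
#' @param fps video frame rate, frames/s.
#' @param calibration a [calibration_model()] or bare factor in m/s.
#' @param waggle_freq_hz waggle oscillation frequency, Hz.
#' @param max_signal_hz highest frequency the video must resolve, Hz.
#' @return list: `ring_spacing_m`, `ring_spacing_m_rounded`,
#'   `waggle_accuracy_m`, `waggle_accuracy_m_rounded`, `nyquist_margin`,
#'   `nyquist_adequate`, `sampling_sufficient`.
#' @export
#' @examples
#' diagnose(60, 380, 13, 18)
diagnose <- function(fps, calibration, waggle_freq_hz, max_signal_hz) {
  rs <- ring_spacing(calibration, fps)
  wa <- waggle_accuracy(calibration, waggle_freq_hz)
  nm <- nyquist_margin(fps, max_signal_hz)
  list(ring_spacing_m = rs$spacing_m,
       ring_spacing_m_rounded = rs$spacing_m_rounded,
       waggle_accuracy_m = wa$accuracy_m,
       waggle_accuracy_m_rounded = wa$accuracy_m_rounded,
       nyquist_margin = nm$ratio,
       nyquist_adequate = nm$adequate,
       sampling_sufficient = rs$spacing_m <= wa$accuracy_m)
}

#' Run the whole decoding pipeline on a phase CSV
#'
#' Reads and validates the phases, aggregates dances, calibrates (or takes
#' the configured factor), geocodes phase- and dance-level endpoints,
#' builds the density map and search-area summary, and writes the artifact
#' bundle into `out_dir`: `dances.csv`, `endpoints_phases.csv/.geojson`,
#' `endpoints_dances.csv/.geojson`, `density.asc` (+ CRS sidecar),
#' `report.json` and `run.log` (a config echo; no wall-clock content, so
#' reruns on identical inputs are byte-identical).
#'
#' @param config a [run_config()].
#' @param phase_csv path to the input phase CSV ([read_phases()] format).
#' @param out_dir output directory, created if needed.
#' @return the report (also written as JSON), invisibly.
#' @export
run_pipeline <- function(config, phase_csv, out_dir) {
  if (!inherits(config, "run_config")) abort_config("not a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  site <- config$site

  stage <- "read_phases"
  report <- tryCatch({
    phases <- read_phases(phase_csv)
    if (nrow(phases) == 0L) abort_validation("phase file contains no rows")

    stage <- "phases_to_dances"
    dances <- phases_to_dances(phases, site$fps)

    stage <- "calibrate"
    cal <- if (!is.null(config$v)) {
      calibration_model(config$v)
    } else {
      durs <- switch(config$estimator, median = dances$duration_median_s,
                     mean = dances$duration_mean_s)
      calibrate(durs, config$feeder_distance_m, estimator = config$estimator)
    }

    stage <- "geocode"
    ep_ph <- geocode_phases(phases, site, cal)
    ep_dn <- geocode_dances(dances, site, cal,
                            duration_estimator = config$estimator)

    stage <- "map"
    grid <- density_map(ep_dn, site, bandwidth_m = config$bandwidth_m,
                        cell_size_m = config$cell_size_m)
    sa <- search_area(grid, ep_dn, trim_fraction = config$trim_fraction)

    stage <- "diagnose"
    diag <- diagnose(site$fps, cal, config$waggle_freq_hz,
                     config$max_signal_hz)
    span_min <- if (!is.null(config$session_len_min)) config$session_len_min
      else max(1e-9, diff(range(as.numeric(phases$timestamp_utc))) / 60)
    rate <- dance_rate(nrow(dances), span_min)

    stage <- "write"
    write_dances(dances, file.path(out_dir, "dances.csv"))
    write_endpoints_csv(ep_ph, file.path(out_dir, "endpoints_phases.csv"))
    write_endpoints_csv(ep_dn, file.path(out_dir, "endpoints_dances.csv"))
    write_endpoints_geojson(ep_ph, file.path(out_dir, "endpoints_phases.geojson"))
    write_endpoints_geojson(ep_dn, file.path(out_dir, "endpoints_dances.geojson"))
    write_asc(grid, file.path(out_dir, "density.asc"))

    rep <- list(
      n_phases = nrow(phases),
      n_dances = nrow(dances),
      dance_rate_per_min = rate$rate,
      dance_rate_rounded = rate$rate_rounded,
      calibration = list(v = cal$v, v_rounded = cal$v_rounded,
                         estimator = cal$estimator, n = cal$n),
      diagnostics = diag,
      sector_width_deg = sector_width(ep_ph$bearing_deg,
                                      config$coverage_fraction),
      coverage_fraction = config$coverage_fraction,
      search_area = list(peak_lat_deg = sa$peak_lat_deg,
                         peak_lon_deg = sa$peak_lon_deg,
                         center_lat_deg = sa$center_lat_deg,
                         center_lon_deg = sa$center_lon_deg,
                         diameter_m = sa$diameter_m,
                         n_endpoints = sa$n_endpoints)
    )
    validate_report(rep)
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c("wagglemap run", "config:",
                 paste0("  ", config_echo(config)),
                 sprintf("input: %s", basename(phase_csv)),
                 sprintf("stages completed: read_phases phases_to_dances calibrate geocode map diagnose write")),
               file.path(out_dir, "run.log"))
    rep
  }, wagglemap_error = function(e) {
    stop(errorCondition(sprintf("stage '%s': %s", stage, conditionMessage(e)),
                        class = class(e)))
  })
  invisible(report)
}

config_echo <- function(config) {
  flat <- c(
    sprintf("site.lat_deg = %.6f", config$site$lat_deg),
    sprintf("site.lon_deg = %.6f", config$site$lon_deg),
    sprintf("site.fps = %g", config$site$fps),
    sprintf("site.utc_offset_h = %g", config$site$utc_offset_h),
    sprintf("calibration = %s",
            if (!is.null(config$v)) sprintf("v %g m/s", config$v)
            else sprintf("feeder %g m (%s)", config$feeder_distance_m,
                         config$estimator)),
    sprintf("bandwidth_m = %g", config$bandwidth_m),
    sprintf("cell_size_m = %g", config$cell_size_m),
    sprintf("trim_fraction = %g", config$trim_fraction),
    sprintf("coverage_fraction = %g", config$coverage_fraction),
    sprintf("waggle_freq_hz = %g", config$waggle_freq_hz),
    sprintf("max_signal_hz = %g", config$max_signal_hz)
  )
  flat
}

#' Structural validation of a pipeline report
#'
#' Checks a report produced by [run_pipeline()] against the JSON schema
#' shipped at `system.file("schema/report.schema.json", package =
#' "wagglemap")`: required fields present, correct types, counts
#' non-negative. Returns the report invisibly or raises a validation
#' error.
#'
#' @param report a report list.
#' @return the report, invisibly.
#' @export
validate_report <- function(report) {
  need_num <- function(path, x) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      abort_validation(sprintf("report field '%s' must be a single number", path))
  }
  for (f in c("n_phases", "n_dances", "dance_rate_per_min", "sector_width_deg"))
    need_num(f, report[[f]])
  if (report$n_phases < 0 || report$n_dances < 0)
    abort_validation("counts must be non-negative")
  if (!is.list(report$calibration)) abort_validation("missing calibration block")
  need_num("calibration.v", report$calibration$v)
  if (!is.list(report$diagnostics)) abort_validation("missing diagnostics block")
  for (f in c("ring_spacing_m", "waggle_accuracy_m", "nyquist_margin"))
    need_num(paste0("diagnostics.", f), report$diagnostics[[f]])
  if (!is.logical(report$diagnostics$sampling_sufficient))
    abort_validation("diagnostics.sampling_sufficient must be logical")
  if (!is.list(report$search_area)) abort_validation("missing search_area block")
  for (f in c("peak_lat_deg", "peak_lon_deg", "diameter_m"))
    need_num(paste0("search_area.", f), report$search_area[[f]])
  if (report$search_area$diameter_m < 0)
    abort_validation("search_area.diameter_m must be >= 0")
  invisible(report)
}
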