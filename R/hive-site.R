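#' Describe the hive site
#'
#' Geographic and optical context for a recording hive: where it stands
#' (so solar azimuth and endpoint projection are possible), the video frame
#' rate (so frame-timed durations become seconds), the local UTC offset
#' (so wall-clock session times become unambiguous instants) and the inner
#' width of the dance-floor frame (for pixel-scale arithmetic).
#'
#' @param lat_deg latitude in degrees, \[-90, 90\].
#' @param lon_deg longitude in degrees, \[-180, 180\], east positive.
#' @param fps video acquisition rate in frames per second (> 0). Default 60.
#' @param utc_offset_h local-time offset from UTC in hours. Default 0.
#' @param frame_inner_width_mm inner width of the comb frame in mm (> 0);
#'   the default 410 is the long side of a Dadant brood frame.
#' @return an object of class `hive_site`.
#' @export
#' @examples
#' hive_site(46.15, -0.64, fps = 60, utc_offset_h = 2)
hive_site <- function(lat_deg, lon_deg, fps = 60, utc_offset_h = 0,
                      frame_inner_width_mm = 410) {
  if (!is.numeric(lat_deg) || length(lat_deg) != 1L || is.na(lat_deg) ||
      lat_deg < -90 || lat_deg > 90)
    abort_invalid("lat_deg must be a single value in [-90, 90]")
  if (!is.numeric(lon_deg) || length(lon_deg) != 1L || is.na(lon_deg) ||
      lon_deg < -180 || lon_deg > 180)
    abort_invalid("lon_deg must be a single value in [-180, 180]")
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0)
    abort_invalid("fps must be a single positive number")
  if (!is.numeric(utc_offset_h) || length(utc_offset_h) != 1L || is.na(utc_offset_h))
    abort_invalid("utc_offset_h must be a single number")
  if (!is.numeric(frame_inner_width_mm) || length(frame_inner_width_mm) != 1L ||
      is.na(frame_inner_width_mm) || frame_inner_width_mm <= 0)
    abort_invalid("frame_inner_width_mm must be a single positive number")
  structure(
    list(lat_deg = as.numeric(lat_deg), lon_deg = as.numeric(lon_deg),
         fps = as.numeric(fps), utc_offset_h = as.numeric(utc_offset_h),
         frame_inner_width_mm = as.numeric(frame_inner_width_mm)),
    class = "hive_site"
  )
}

#' @export
print.hive_site <- function(x, ...) {
  cat(sprintf("<hive_site> lat %.5f, lon %.5f, %g fps, UTC%+g, frame %g mm\n",
              x$lat_deg, x$lon_deg, x$fps, x$utc_offset_h,
              x$frame_inner_width_mm))
  invisible(x)
}

is_hive_site <- function(x) inherits(x, "hive_site")

assert_hive_site <- function(x) {
  if (!is_hive_site(x)) abort_invalid("`site` must be a hive_site object")
  invisible(x)
}
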