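#' Aggregate waggle phases into dances
#'
#' A dance is a figure-eight bout made of repeated waggle phases. Direction
#' is summarized by the circular (vector-sum) mean of the phase angles;
#' duration by the median (eta), mean (mu) and standard deviation (sigma)
#' of the frame-timed phase durations. The dance timestamp is the instant
#' of its first phase (smallest `phase_index`).
#'
#' When a dance's phase angles cancel exactly (mean resultant length 0) the
#' circular mean is undefined; `mean_angle_deg` is `NA` and `mean_defined`
#' is `FALSE` rather than reporting an arbitrary direction.
#'
#' @param phases a `waggle_phases` table (see [waggle_phases()]).
#' @param fps acquisition rate in frames per second used to convert frame
#'   differences to seconds.
#' @return a tibble of class `dances` with one row per `dance_id`:
#'   `dance_id`, `n_phases`, `mean_angle_deg`, `mean_defined`,
#'   `resultant_length`, `duration_median_s`, `duration_mean_s`,
#'   `duration_sd_s` (`NA` for single-phase dances), `timestamp_utc`.
#' @export
#' @examples
#' ph <- waggle_phases("d1", 0:2, c(0, 100, 200), c(36, 140, 236),
#'                     c(90, 90, 90), rep("2022-06-21T10:49:00Z", 3))
#' phases_to_dances(ph, fps = 60)
phases_to_dances <- function(phases, fps) {
  phases <- validate_phases(as_tibble(phases))
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0)
    abort_invalid("fps must be a single positive number")
  if (nrow(phases) == 0L) {
    out <- tibble(dance_id = character(), n_phases = integer(),
                  mean_angle_deg = numeric(), mean_defined = logical(),
                  resultant_length = numeric(), duration_median_s = numeric(),
                  duration_mean_s = numeric(), duration_sd_s = numeric(),
                  timestamp_utc = .POSIXct(numeric(), tz = "UTC"))
    class(out) <- unique(c("dances", class(out)))
    return(out)
  }
  phases$duration_s <- duration_from_frames(phases$frame_start,
                                            phases$frame_end, fps)
  out <- phases |>
    dplyr::group_by(dance_id) |>
    dplyr::arrange(phase_index, .by_group = TRUE) |>
    dplyr::summarise(
      n_phases = dplyr::n(),
      mean_angle_deg = circular_mean_deg(angle_deg)$mean_deg,
      mean_defined = circular_mean_deg(angle_deg)$defined,
      resultant_length = circular_mean_deg(angle_deg)$resultant_length,
      duration_median_s = stats::median(duration_s),
      duration_mean_s = mean(duration_s),
      duration_sd_s = stats::sd(duration_s),
      timestamp_utc = timestamp_utc[1L],
      .groups = "drop"
    ) |>
    dplyr::arrange(timestamp_utc, dance_id)
  class(out) <- unique(c("dances", class(out)))
  out
}

#' Dance rate over an observation window
#'
#' Dances per minute, the throughput statistic used to judge whether the
#' dance floor is well placed in front of the camera.
#'
#' @param n_dances number of dances observed (>= 0).
#' @param duration_min observation duration in minutes (> 0).
#' @return list with `rate` (dances/min) and `rate_rounded` (nearest integer).
#' @export
#' @examples
#' dance_rate(141, 10)  # 14.1, rounded 14
dance_rate <- function(n_dances, duration_min) {
  if (!is.numeric(n_dances) || length(n_dances) != 1L || is.na(n_dances) ||
      n_dances < 0)
    abort_invalid("n_dances must be a single non-negative number")
  if (!is.numeric(duration_min) || length(duration_min) != 1L ||
      is.na(duration_min) || duration_min <= 0)
    abort_invalid("duration_min must be a single positive number")
  rate <- n_dances / duration_min
  list(rate = rate, rate_rounded = as.integer(round(rate)))
}

#' Write a dance summary CSV
#'
#' Columns: `dance_id,n_phases,mean_angle_deg,duration_median_s,`
#' `duration_mean_s,duration_sd_s,timestamp_utc` (ISO-8601 UTC).
#'
#' @param dances a `dances` table from [phases_to_dances()].
#' @param path output CSV path.
#' @return the input, invisibly.
#' @export
write_dances <- function(dances, path) {
  out <- as_tibble(dances)[, c("dance_id", "n_phases", "mean_angle_deg",
                               "duration_median_s", "duration_mean_s",
                               "duration_sd_s", "timestamp_utc")]
  out$timestamp_utc <- format_utc(out$timestamp_utc)
  readr::write_csv(out, path, progress = FALSE)
  invisible(dances)
}
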