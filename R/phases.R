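#' Waggle-phase duration from frame indices
#'
#' A decoded phase is timed by its start and end video frames; the duration
#' in seconds is the frame difference divided by the acquisition rate. The
#' result is therefore always an exact multiple of `1/fps` — this frame
#' quantization is what produces the concentric distance rings on endpoint
#' maps (see [ring_spacing()]).
#'
#' @param frame_start,frame_end integer frame indices, `frame_end > frame_start`.
#' @param fps acquisition rate in frames per second (> 0).
#' @return duration in seconds, vectorized over the frame arguments.
#' @export
#' @examples
#' duration_from_frames(0, 36, 60)   # 0.60 s
duration_from_frames <- function(frame_start, frame_end, fps) {
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0)
    abort_invalid("fps must be a single positive number")
  if (length(frame_start) != length(frame_end))
    abort_invalid("frame_start and frame_end must have equal length")
  if (any(is.na(frame_start)) || any(is.na(frame_end)))
    abort_invalid("frame indices must not be NA")
  if (any(frame_end <= frame_start))
    abort_invalid("frame_end must be strictly greater than frame_start")
  (frame_end - frame_start) / fps
}

phase_columns <- c("dance_id", "phase_index", "frame_start", "frame_end",
                   "angle_deg", "timestamp_utc")

#' Build a validated waggle-phase table
#'
#' One row per waggle run: which dance it belongs to, its order within the
#' dance, its start/end video frames, its angle from the vertical (degrees,
#' clockwise positive, \[0, 360)) and the UTC instant it occurred. All
#' downstream operations take this table as input.
#'
#' @param dance_id character (or coercible) dance labels.
#' @param phase_index integer phase order within each dance (>= 0).
#' @param frame_start,frame_end integer frame indices, `frame_end > frame_start`.
#' @param angle_deg angle from vertical in degrees, in \[0, 360).
#' @param timestamp_utc `POSIXct` instants (converted to UTC) or ISO-8601 strings.
#' @return a tibble of class `waggle_phases`.
#' @export
waggle_phases <- function(dance_id, phase_index, frame_start, frame_end,
                          angle_deg, timestamp_utc) {
  ts <- parse_utc(timestamp_utc)
  if (any(is.na(ts))) abort_validation("unparsable timestamp_utc values")
  x <- tibble(
    dance_id = as.character(dance_id),
    phase_index = as.integer(phase_index),
    frame_start = as.integer(frame_start),
    frame_end = as.integer(frame_end),
    angle_deg = as.numeric(angle_deg),
    timestamp_utc = ts
  )
  validate_phases(x)
}

validate_phases <- function(x, file_lines = FALSE) {
  missing <- setdiff(phase_columns, names(x))
  if (length(missing) > 0L)
    abort_validation(paste0("missing phase columns: ",
                            paste(missing, collapse = ", ")))
  # rows reported 1-based over data rows; +1 when they came from a CSV body
  off <- if (file_lines) 1L else 0L
  bad <- function(rows, what) {
    if (length(rows) > 0L)
      abort_validation(sprintf("%s (rows %s)", what,
                               paste(rows + off, collapse = ", ")))
  }
  bad(which(is.na(x$dance_id) | x$dance_id == ""), "empty dance_id")
  bad(which(is.na(x$phase_index) | x$phase_index < 0L), "phase_index must be >= 0")
  bad(which(is.na(x$frame_start) | is.na(x$frame_end) |
              x$frame_end <= x$frame_start),
      "frame_end must be strictly greater than frame_start")
  bad(which(is.na(x$angle_deg) | x$angle_deg < 0 | x$angle_deg >= 360),
      "angle_deg out of range [0, 360)")
  bad(which(is.na(x$timestamp_utc)), "unparsable timestamp_utc")
  dup <- duplicated(x[, c("dance_id", "phase_index")])
  bad(which(dup), "duplicated (dance_id, phase_index)")
  class(x) <- unique(c("waggle_phases", class(x)))
  x
}

parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")) {
    todo <- is.na(out) & !is.na(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(sub("Z$", "", x[todo]), fmt, tz = "UTC"))
  }
  out
}

format_utc <- function(ts) {
  # whole-second serialization: solar azimuth drifts only ~2-3 degrees per
  # 10 min, so sub-second wall-clock carries no geolocation information
  format(.POSIXct(round(as.numeric(ts)), tz = "UTC"),
         "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Read and write waggle-phase CSV files
#'
#' The on-disk interchange format is a UTF-8 CSV with header
#' `dance_id,phase_index,frame_start,frame_end,angle_deg,timestamp_utc`
#' (timestamps ISO-8601, UTC). Malformed rows are reported with their row
#' numbers. `write_phases()` serializes timestamps at whole-second
#' resolution, and `read_phases(write_phases(x))` reproduces `x` exactly for
#' such timestamps. A file containing only the header yields an empty table.
#'
#' @param path path to a phase CSV file.
#' @param phases a `waggle_phases` table (see [waggle_phases()]).
#' @return `read_phases()`: a validated `waggle_phases` tibble.
#'   `write_phases()`: the input, invisibly.
#' @export
read_phases <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               col_types = readr::cols(.default = readr::col_character())))
  missing <- setdiff(phase_columns, hdr)
  if (length(missing) > 0L)
    abort_validation(paste0("missing phase columns in ", path, ": ",
                            paste(missing, collapse = ", ")))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      dance_id = readr::col_character(),
      phase_index = readr::col_integer(),
      frame_start = readr::col_integer(),
      frame_end = readr::col_integer(),
      angle_deg = readr::col_double(),
      timestamp_utc = readr::col_character()
    ),
    progress = FALSE
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0L)
    abort_validation(sprintf("unparsable values in %s (rows %s)", path,
                             paste(unique(prob$row), collapse = ", ")))
  raw$timestamp_utc <- parse_utc(raw$timestamp_utc)
  validate_phases(raw, file_lines = TRUE)
}

#' @rdname read_phases
#' @export
write_phases <- function(phases, path) {
  phases <- validate_phases(as_tibble(phases))
  out <- phases
  out$timestamp_utc <- format_utc(out$timestamp_utc)
  readr::write_csv(as_tibble(out), path, progress = FALSE)
  invisible(phases)
}
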