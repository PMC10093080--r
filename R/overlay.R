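#' Static grid-overlay line coordinates for a video frame
#'
#' Frame-by-frame visual decoding is done grid cell by grid cell; this
#' returns the pixel coordinates of the overlay lines (rendering is left to
#' the caller). Lines sit at positive multiples of `cell_px` strictly
#' inside the frame, so a cell size at least as large as a dimension yields
#' no line in that dimension.
#'
#' @param video_w_px,video_h_px frame size in pixels (positive integers).
#' @param cell_px grid cell edge in pixels (positive integer).
#' @return list with integer vectors `vertical` (x positions) and
#'   `horizontal` (y positions).
#' @export
#' @examples
#' grid_overlay(1280, 720, 128)  # 9 vertical, 5 horizontal lines
grid_overlay <- function(video_w_px, video_h_px, cell_px) {
  for (v in c(video_w_px, video_h_px, cell_px))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 ||
        v != round(v))
      abort_invalid("grid_overlay arguments must be positive integers")
  vx <- seq.int(cell_px, by = cell_px,
                length.out = max(0L, floor((video_w_px - 1) / cell_px)))
  hy <- seq.int(cell_px, by = cell_px,
                length.out = max(0L, floor((video_h_px - 1) / cell_px)))
  list(vertical = as.integer(vx), horizontal = as.integer(hy))
}

#' Pixel scale of the dance-floor video
#'
#' `pixel_scale()` is the spatial resolution (px/mm) from a pixel extent
#' and the physical extent it images; `object_px()` is the on-screen size
#' of an object, rounded to whole pixels. Which video dimension maps to
#' which physical extent is the caller's choice — the 720p dance-floor
#' video at 1.76 px/mm corresponds to 720 px over a 410 mm frame width.
#'
#' @param px_extent extent in pixels (> 0).
#' @param mm_extent the physical extent imaged, in mm (> 0).
#' @param size_mm object size in mm (> 0).
#' @param scale pixel scale in px/mm (> 0).
#' @return `pixel_scale()`: px/mm; `object_px()`: integer pixels.
#' @export
#' @examples
#' pixel_scale(720, 410)   # ~1.76 px/mm
#' object_px(15, 1.76)     # a 15 mm bee is 26 px
pixel_scale <- function(px_extent, mm_extent) {
  if (!is.numeric(px_extent) || any(px_extent <= 0) ||
      !is.numeric(mm_extent) || any(mm_extent <= 0))
    abort_invalid("extents must be positive")
  px_extent / mm_extent
}

#' @rdname pixel_scale
#' @export
object_px <- function(size_mm, scale) {
  if (!is.numeric(size_mm) || any(size_mm <= 0) ||
      !is.numeric(scale) || any(scale <= 0))
    abort_invalid("size_mm and scale must be positive")
  as.integer(round(size_mm * scale))
}
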