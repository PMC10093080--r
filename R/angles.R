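#' Wrap angles into [0, 360)
#'
#' Dance angles and compass bearings are stored in degrees, clockwise
#' positive, normalized to the half-open interval \[0, 360).
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in \[0, 360).
#' @export
#' @examples
#' wrap_degrees(c(-10, 360, 725))
wrap_degrees <- function(x) {
  out <- x %% 360
  # %% can return 360 for tiny negative floating-point inputs
  out[out >= 360] <- out[out >= 360] - 360
  out
}

#' Signed smallest difference between two angles
#'
#' Returns `a - b` wrapped into (-180, 180], the signed angular separation
#' used for bearing-error summaries.
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @export
angle_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' Circular mean of angles in degrees
#'
#' Vector-sum (first trigonometric moment) mean. When the mean resultant
#' length is numerically zero the direction is undefined and `NA` is
#' returned for the mean.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @param eps resultant lengths below this are treated as undefined.
#' @return list with `mean_deg` (in \[0, 360) or `NA`), `resultant_length`
#'   (mean resultant length in \[0, 1\]) and `defined` (logical).
#' @export
#' @examples
#' circular_mean_deg(c(350, 10))$mean_deg  # 0
circular_mean_deg <- function(angles_deg, eps = 1e-9) {
  if (length(angles_deg) == 0L) abort_invalid("circular mean of an empty angle set")
  rad <- angles_deg * pi / 180
  s <- mean(sin(rad))
  c <- mean(cos(rad))
  r <- sqrt(s^2 + c^2)
  if (r < eps) {
    list(mean_deg = NA_real_, resultant_length = r, defined = FALSE)
  } else {
    list(mean_deg = wrap_degrees(atan2(s, c) * 180 / pi),
         resultant_length = r, defined = TRUE)
  }
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
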