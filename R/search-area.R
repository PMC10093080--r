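#' Summarize the search area of a set of endpoints
#'
#' Two complementary summaries of where the colony is foraging: the density
#' peak (argmax cell of the heat-map grid; ties broken toward the endpoint
#' centroid) and a minimal enclosing circle of the endpoints. With
#' `trim_fraction = 0` (default) the circle contains every endpoint and is
#' a conservative bound on the search area; a positive fraction discards
#' that share of endpoints farthest from the peak before enclosing.
#'
#' @param grid a `density_grid` built from the same endpoints.
#' @param endpoints the `geo_endpoints` tibble the grid was built from.
#' @param trim_fraction fraction in \[0, 1) of endpoints (farthest from the
#'   peak) to discard before computing the enclosing circle. Default 0.
#' @return an object of class `search_area`: `peak_lat_deg`/`peak_lon_deg`,
#'   `center_lat_deg`/`center_lon_deg` and `diameter_m` of the enclosing
#'   circle, and `n_endpoints` actually enclosed.
#' @export
search_area <- function(grid, endpoints, trim_fraction = 0) {
  if (!inherits(grid, "density_grid")) abort_invalid("not a density_grid")
  if (!is.numeric(trim_fraction) || length(trim_fraction) != 1L ||
      is.na(trim_fraction) || trim_fraction < 0 || trim_fraction >= 1)
    abort_invalid("trim_fraction must be in [0, 1)")
  endpoints <- as_tibble(endpoints)
  if (nrow(endpoints) == 0L) abort_invalid("no endpoints")
  site <- grid$site
  tp <- to_tangent(site, endpoints$lat_deg, endpoints$lon_deg)
  cc <- grid_cell_centers(grid)

  peak_val <- max(grid$values)
  idx <- which(grid$values >= peak_val - 1e-9, arr.ind = TRUE)  # [row=y, col=x]
  px <- cc$x[idx[, 2]]
  py <- cc$y[idx[, 1]]
  if (length(px) > 1L) {
    cx <- mean(tp$x); cy <- mean(tp$y)
    k <- which.min((px - cx)^2 + (py - cy)^2)
    px <- px[k]; py <- py[k]
  }

  n <- nrow(tp)
  d_peak <- tangent_dist(tp$x, tp$y, px, py)
  n_drop <- floor(trim_fraction * n)
  keep <- order(d_peak)[seq_len(n - n_drop)]
  circ <- min_enclosing_circle(tp$x[keep], tp$y[keep])

  peak_ll <- from_tangent(site, px, py)
  cen_ll <- from_tangent(site, circ$x, circ$y)
  structure(
    list(peak_lat_deg = peak_ll$lat_deg, peak_lon_deg = peak_ll$lon_deg,
         center_lat_deg = cen_ll$lat_deg, center_lon_deg = cen_ll$lon_deg,
         diameter_m = 2 * circ$r, n_endpoints = length(keep)),
    class = "search_area"
  )
}

#' @export
print.search_area <- function(x, ...) {
  cat(sprintf(
    "<search_area> peak (%.6f, %.6f), circle center (%.6f, %.6f), diameter %.1f m over %d endpoints\n",
    x$peak_lat_deg, x$peak_lon_deg, x$center_lat_deg, x$center_lon_deg,
    x$diameter_m, x$n_endpoints))
  invisible(x)
}

# Minimal enclosing circle, randomized incremental construction: points
# found outside the current circle are promoted to the boundary one at a
# time; with one or two boundary points fixed, the enclosing circle of the
# prefix is rebuilt. With two fixed boundary points the circumcircle must
# be grown separately on each side of their chord (tracking the farthest
# circumcenter per side), otherwise a later point can evict an earlier one.
# Expected linear time after shuffling; the shuffle uses a fixed internal
# permutation so results are deterministic and the caller's RNG untouched.
min_enclosing_circle <- function(x, y) {
  n <- length(x)
  if (n == 0L) abort_invalid("no points")
  if (n == 1L) return(list(x = x[1], y = y[1], r = 0))
  ord <- deterministic_shuffle(n)
  x <- x[ord]; y <- y[ord]
  tol <- 1e-10
  inside <- function(c, i)
    tangent_dist(x[i], y[i], c$x, c$y) <= c$r * (1 + tol) + 1e-12

  one_boundary <- function(i) {
    c <- list(x = x[i], y = y[i], r = 0)
    for (j in seq_len(i - 1L)) {
      if (inside(c, j)) next
      c <- if (c$r == 0) circle2(x[i], y[i], x[j], y[j])
           else two_boundary(i, j)
    }
    c
  }
  two_boundary <- function(i, j) {
    circ <- circle2(x[i], y[i], x[j], y[j])
    left <- NULL; right <- NULL
    px <- x[i]; py <- y[i]
    qx <- x[j] - px; qy <- y[j] - py
    cross_p <- function(ax, ay) qx * (ay - py) - qy * (ax - px)
    for (k in seq_len(j - 1L)) {
      if (inside(circ, k)) next
      cr <- cross_p(x[k], y[k])
      cc <- circumcircle(x[i], y[i], x[j], y[j], x[k], y[k])
      if (is.null(cc)) next
      ccr <- cross_p(cc$x, cc$y)
      if (cr > 0 && (is.null(left) || ccr > cross_p(left$x, left$y))) {
        left <- cc
      } else if (cr < 0 && (is.null(right) || ccr < cross_p(right$x, right$y))) {
        right <- cc
      }
    }
    if (is.null(left) && is.null(right)) circ
    else if (is.null(left)) right
    else if (is.null(right)) left
    else if (left$r <= right$r) left else right
  }

  c <- circle2(x[1], y[1], x[2], y[2])
  for (i in seq_len(n)[-(1:2)]) {
    if (!inside(c, i)) c <- one_boundary(i)
  }
  c
}

circle2 <- function(x1, y1, x2, y2) {
  list(x = (x1 + x2) / 2, y = (y1 + y2) / 2,
       r = tangent_dist(x1, y1, x2, y2) / 2)
}

circumcircle <- function(x1, y1, x2, y2, x3, y3) {
  d <- 2 * (x1 * (y2 - y3) + x2 * (y3 - y1) + x3 * (y1 - y2))
  if (abs(d) < 1e-12) return(NULL)  # collinear: no circumcircle
  ux <- ((x1^2 + y1^2) * (y2 - y3) + (x2^2 + y2^2) * (y3 - y1) +
           (x3^2 + y3^2) * (y1 - y2)) / d
  uy <- ((x1^2 + y1^2) * (x3 - x2) + (x2^2 + y2^2) * (x1 - x3) +
           (x3^2 + y3^2) * (x2 - x1)) / d
  list(x = ux, y = uy, r = tangent_dist(x1, y1, ux, uy))
}

# Fixed linear-congruential permutation so results never depend on (or
# disturb) the caller's RNG state.
deterministic_shuffle <- function(n) {
  s <- 104729
  key <- numeric(n)
  for (i in seq_len(n)) {
    s <- (69069 * s + 1) %% 4294967296  # products stay below 2^53
    key[i] <- s
  }
  order(key)
}
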