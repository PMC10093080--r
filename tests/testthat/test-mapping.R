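test_that("a single endpoint produces a peak of 100 at its own cell", {
  s <- test_site()
  ep <- endpoints_at(s, 100, 50)
  g <- density_map(ep, s, bandwidth_m = 29, cell_size_m = 5)
  expect_equal(max(g$values), 100)
  expect_true(all(g$values >= 0 & g$values <= 100))
  idx <- which(g$values == max(g$values), arr.ind = TRUE)
  cc <- wagglemap:::grid_cell_centers(g)
  expect_lt(abs(cc$x[idx[1, 2]] - 100), g$cell_size_m)
  expect_lt(abs(cc$y[idx[1, 1]] - 50), g$cell_size_m)
})

test_that("two well-separated endpoints give two equal local maxima", {
  s <- test_site()
  ep <- endpoints_at(s, c(0, 0), c(0, 290))  # 10 bandwidths apart
  g <- density_map(ep, s, bandwidth_m = 29, cell_size_m = 5)
  peaks <- which(g$values > 99.99)
  expect_gte(length(peaks), 2L)
  cc <- wagglemap:::grid_cell_centers(g)
  rows <- ((peaks - 1) %% g$n_y) + 1
  expect_setequal(round(sort(cc$y[rows]) / 5) * 5, c(0, 290))
})

test_that("the density argmax tracks the sample centroid of a point cloud", {
  s <- test_site()
  set.seed(13)
  x <- rnorm(1000, 150, 40)
  y <- rnorm(1000, -80, 40)
  ep <- endpoints_at(s, x, y)
  g <- density_map(ep, s, bandwidth_m = 29, cell_size_m = 5)
  idx <- which(g$values == max(g$values), arr.ind = TRUE)[1, ]
  cc <- wagglemap:::grid_cell_centers(g)
  expect_lt(abs(cc$x[idx[2]] - mean(x)), 2 * g$cell_size_m)
  expect_lt(abs(cc$y[idx[1]] - mean(y)), 2 * g$cell_size_m)
})

test_that("density values agree with MASS::kde2d on the same grid", {
  s <- test_site()
  set.seed(21)
  x <- rnorm(120, 0, 60); y <- rnorm(120, 200, 60)
  ep <- endpoints_at(s, x, y)
  bw <- 25
  g <- density_map(ep, s, bandwidth_m = bw, cell_size_m = 10)
  cc <- wagglemap:::grid_cell_centers(g)
  tp <- wagglemap:::to_tangent(s, ep$lat_deg, ep$lon_deg)
  # MASS parameterizes the normal kernel as sd = h/4
  k <- MASS::kde2d(tp$x, tp$y, h = 4 * bw, n = c(g$n_x, g$n_y),
                   lims = c(range(cc$x), range(cc$y)))
  want <- t(k$z) * 100 / max(k$z)   # kde2d z is [x, y]; grid values are [y, x]
  expect_equal(g$values, want, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("density is stable under a rigid translation of all endpoints", {
  s <- test_site()
  set.seed(33)
  ep <- endpoints_at(s, rnorm(150, 0, 50), rnorm(150, 230, 50))
  g1 <- density_map(ep, s, bandwidth_m = 29, cell_size_m = 5)
  shifted <- geosphere::destPoint(cbind(ep$lon_deg, ep$lat_deg), 0, 500,
                                  r = 6371000)
  ep2 <- ep
  ep2$lon_deg <- shifted[, "lon"]; ep2$lat_deg <- shifted[, "lat"]
  g2 <- density_map(ep2, s, bandwidth_m = 29, cell_size_m = 5)
  expect_equal(dim(g1$values), dim(g2$values))
  expect_lt(max(abs(g1$values - g2$values)), 1)  # < 1% of the peak (=100)
})

test_that("the enclosing circle is minimal and contains every kept endpoint", {
  s <- test_site()

  one <- endpoints_at(s, 40, -25)
  g1 <- density_map(one, s)
  sa1 <- search_area(g1, one)
  expect_equal(sa1$diameter_m, 0)
  expect_equal(sa1$peak_lat_deg, one$lat_deg, tolerance = 1e-4)

  two <- endpoints_at(s, c(0, 100), c(0, 0))
  g2 <- density_map(two, s)
  sa2 <- search_area(g2, two)
  expect_equal(sa2$diameter_m, 100, tolerance = 1e-6)
  mid <- wagglemap:::to_tangent(s, sa2$center_lat_deg, sa2$center_lon_deg)
  expect_equal(c(mid$x, mid$y), c(50, 0), tolerance = 1e-6)

  # random clouds: agree with the brute-force oracle; contain all points
  set.seed(55)
  for (rep in 1:5) {
    r <- 87.5 * sqrt(runif(50)); th <- runif(50, 0, 2 * pi)
    x <- 100 + r * cos(th); y = -40 + r * sin(th)
    ep <- endpoints_at(s, x, y)
    g <- density_map(ep, s, cell_size_m = 10)
    sa <- search_area(g, ep)
    expect_lte(sa$diameter_m, 175 + 1e-6)
    want <- oracle_mec(x, y)
    expect_equal(sa$diameter_m, 2 * want$r, tolerance = 1e-6)
    cen <- wagglemap:::to_tangent(s, sa$center_lat_deg, sa$center_lon_deg)
    d <- sqrt((x - cen$x)^2 + (y - cen$y)^2)
    expect_true(all(d <= sa$diameter_m / 2 + 0.01))  # 1 cm tolerance
  }
})

test_that("trimming drops the farthest endpoints before enclosing", {
  s <- test_site()
  x <- c(rep(0, 9), 1000)  # one far outlier
  y <- c(seq(-20, 20, length.out = 9), 0)
  ep <- endpoints_at(s, x, y)
  g <- density_map(ep, s)
  full <- search_area(g, ep, trim_fraction = 0)
  trimmed <- search_area(g, ep, trim_fraction = 0.1)
  expect_gt(full$diameter_m, 900)
  expect_lt(trimmed$diameter_m, 50)
  expect_equal(trimmed$n_endpoints, 9L)
})

test_that("grid overlay line counts follow the floor expressions", {
  ov <- grid_overlay(1280, 720, 128)
  expect_length(ov$vertical, 9L)
  expect_length(ov$horizontal, 5L)
  expect_equal(ov$vertical[1], 128L)
  expect_length(grid_overlay(100, 100, 200)$vertical, 0L)
  ov2 <- grid_overlay(1280, 720, 640)
  expect_length(ov2$vertical, 1L)
  expect_length(ov2$horizontal, 1L)
  expect_error(grid_overlay(0, 720, 128), class = "wagglemap_invalid_input")

  set.seed(66)
  for (rep in 1:25) {
    w <- sample(50:4000, 1); h <- sample(50:4000, 1); c <- sample(10:900, 1)
    ov <- grid_overlay(w, h, c)
    expect_length(ov$vertical, floor((w - 1) / c))
    expect_length(ov$horizontal, floor((h - 1) / c))
    expect_true(all(ov$vertical < w) && all(ov$horizontal < h))
  }
})

test_that("pixel-scale arithmetic reproduces the screen size of a bee", {
  expect_equal(round(pixel_scale(720, 410), 2), 1.76)
  expect_equal(object_px(15, 1.76), 26L)
  expect_equal(pixel_scale(410, 410), 1)
  expect_error(pixel_scale(0, 410), class = "wagglemap_invalid_input")
  expect_error(object_px(-1, 2), class = "wagglemap_invalid_input")
})

test_that("the ESRI ASCII export round-trips the grid values", {
  s <- test_site()
  set.seed(3)
  ep <- endpoints_at(s, rnorm(30, 0, 30), rnorm(30, 100, 30))
  g <- density_map(ep, s, cell_size_m = 10)
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(g, path)
  lines <- readLines(path)
  expect_match(lines[1], sprintf("^ncols %d$", g$n_x))
  expect_match(lines[2], sprintf("^nrows %d$", g$n_y))
  vals <- do.call(rbind, lapply(lines[-(1:6)],
                                function(l) as.numeric(strsplit(l, " ")[[1]])))
  expect_equal(dim(vals), c(g$n_y, g$n_x))
  # row 1 of the file is the northernmost grid row
  expect_equal(vals[g$n_y, ], unname(g$values[1, ]), tolerance = 1e-6)
  expect_true(file.exists(paste0(path, ".crs.json")))
})
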