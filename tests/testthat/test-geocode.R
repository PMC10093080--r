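test_that("dance angle plus solar azimuth gives a wrapped compass bearing", {
  expect_equal(bearing_from_dance(0, 137), 137)
  expect_equal(bearing_from_dance(90, 180), 270)
  expect_equal(bearing_from_dance(350, 20), 10)
  expect_error(bearing_from_dance(Inf, 10), class = "wagglemap_invalid_input")
})

test_that("duration maps to distance linearly through the calibration factor", {
  cal <- calibration_model(383.33)
  expect_equal(distance_from_duration(0.60, cal), 229.998)
  expect_equal(distance_from_duration(0, cal), 0)
  expect_equal(distance_from_duration(1.2, cal),
               2 * distance_from_duration(0.6, cal))
  set.seed(5)
  tau <- runif(20, 0, 2)
  k <- runif(20, 0, 5)
  expect_equal(distance_from_duration(k * tau, cal),
               k * distance_from_duration(tau, cal))
  expect_error(distance_from_duration(-1, cal),
               class = "wagglemap_invalid_input")
})

test_that("calibration divides known distance by the duration summary", {
  cal <- calibrate(c(0.55, 0.60, 0.80), 230)
  expect_equal(cal$v, 230 / 0.60)
  expect_equal(cal$v_rounded, 380)
  expect_equal(calibrate(c(0.5, 0.6, 0.7), 300)$v, 500)
  expect_equal(calibrate(rep(0.4, 7), 200)$v, 500)
  expect_equal(calibrate(c(0.5, 0.6, 0.7), 300, estimator = "mean")$v, 500)
  expect_error(calibrate(numeric(), 230), class = "wagglemap_invalid_input")
  expect_error(calibrate(c(0, 0), 230), class = "wagglemap_invalid_input")
  expect_error(calibrate(c(0.5), 0), class = "wagglemap_invalid_input")

  # calibrate then decode the summary duration -> the known distance, exactly
  set.seed(31)
  for (rep in 1:10) {
    durs <- runif(sample(3:40, 1), 0.2, 1.5)
    D <- runif(1, 50, 2000)
    expect_equal(distance_from_duration(median(durs), calibrate(durs, D)), D)
  }
})

test_that("endpoint projection matches the closed-form spherical destination", {
  eq <- hive_site(0, 0)
  e <- project_endpoint(eq, 90, 111195)
  expect_equal(e$lat_deg, 0, tolerance = 1e-6)
  expect_equal(e$lon_deg, 1.0, tolerance = 1e-6)

  # distance zero is the hive, bit-exactly
  s <- test_site()
  e0 <- project_endpoint(s, 123, 0)
  expect_identical(e0$lat_deg, s$lat_deg)
  expect_identical(e0$lon_deg, s$lon_deg)

  # north/south symmetry about an equatorial hive
  en <- project_endpoint(eq, 0, 5000)
  es <- project_endpoint(eq, 180, 5000)
  expect_equal(en$lat_deg, -es$lat_deg, tolerance = 1e-10)
  expect_equal(en$lon_deg, es$lon_deg, tolerance = 1e-10)

  # < 0.1 m agreement with the oracle for random sites, bearings, d <= 10 km
  set.seed(77)
  for (i in 1:200) {
    site <- hive_site(runif(1, -70, 70), runif(1, -179, 179))
    b <- runif(1, 0, 360); d <- runif(1, 0, 10000)
    got <- project_endpoint(site, b, d)
    want <- oracle_destination(site$lat_deg, site$lon_deg, b, d)
    err <- geosphere::distHaversine(c(got$lon_deg, got$lat_deg),
                                 c(want["lon"], want["lat"]), r = 6371000)
    expect_lt(err, 0.1)
  }
})

test_that("sampling and accuracy diagnostics follow their closed forms", {
  wa <- waggle_accuracy(380, 13)
  expect_equal(wa$accuracy_m, 380 / 13)
  expect_equal(wa$accuracy_m_rounded, 29L)
  expect_equal(waggle_accuracy(380, 380)$accuracy_m, 1)
  expect_equal(waggle_accuracy(500, 12.5)$accuracy_m, 40)
  expect_error(waggle_accuracy(380, 0), class = "wagglemap_invalid_input")

  rs <- ring_spacing(380, 60)
  expect_equal(rs$spacing_m, 380 / 60)
  expect_equal(rs$spacing_m_rounded, 6L)
  expect_equal(ring_spacing(380, 120)$spacing_m, 380 / 120)
  expect_equal(ring_spacing(60, 60)$spacing_m, 1)
  expect_error(ring_spacing(380, -1), class = "wagglemap_invalid_input")

  nm <- nyquist_margin(60, 18)
  expect_equal(nm$ratio, 60 / 36)
  expect_true(nm$adequate)
  expect_true(nyquist_margin(60, 30)$adequate)   # boundary counts as adequate
  bad <- nyquist_margin(25, 13)
  expect_equal(bad$ratio, 25 / 26)
  expect_false(bad$adequate)
  expect_error(nyquist_margin(0, 13), class = "wagglemap_invalid_input")
})

test_that("sector width is the narrowest anchored arc covering the bearings", {
  expect_equal(sector_width(rep(123.4, 10), 1.0), 0)
  expect_equal(sector_width(c(0, 10, 20, 350), 1.0), 30)  # arc 350 -> 20
  expect_gt(sector_width(seq(0, 359, by = 1), 1.0), 350)  # near-uniform circle
  expect_error(sector_width(numeric()), class = "wagglemap_invalid_input")
  expect_error(sector_width(c(1, 2), 0), class = "wagglemap_invalid_input")

  # brute-force oracle agreement on random bearing sets and coverages
  set.seed(88)
  for (rep in 1:25) {
    b <- runif(sample(3:40, 1), 0, 360)
    cov <- sample(c(0.5, 0.8, 0.95, 1.0), 1)
    expect_equal(sector_width(b, cov), oracle_sector(b, cov),
                 tolerance = 1e-9)
  }
})

test_that("geocoded endpoints rotate with the solar azimuth and keep distance", {
  s <- test_site()
  set.seed(64)
  ph <- make_phases(4, 5, angle = runif(20, 0, 360),
                    frames = sample(30:45, 20, TRUE))
  cal <- calibration_model(380)
  ep <- geocode_phases(ph, s, cal)

  # rotating every angle by delta rotates every bearing by delta and
  # leaves the hive distance unchanged (solar azimuth enters additively)
  delta <- 37.5
  ph2 <- ph
  ph2$angle_deg <- wrap_degrees(ph2$angle_deg + delta)
  ep2 <- geocode_phases(ph2, s, cal)
  expect_equal(wrap_degrees(ep2$bearing_deg - ep$bearing_deg),
               rep(delta, nrow(ep)), tolerance = 1e-9)
  expect_equal(ep2$distance_m, ep$distance_m)
  d1 <- geosphere::distHaversine(c(s$lon_deg, s$lat_deg),
                              cbind(ep$lon_deg, ep$lat_deg), r = 6371000)
  d2 <- geosphere::distHaversine(c(s$lon_deg, s$lat_deg),
                              cbind(ep2$lon_deg, ep2$lat_deg), r = 6371000)
  expect_equal(d1, d2, tolerance = 1e-6)

  # frame-quantized durations put endpoint distances on the v/fps ring grid
  ring <- ring_spacing(cal, s$fps)$spacing_m
  expect_equal(ep$distance_m / ring, round(ep$distance_m / ring),
               tolerance = 1e-9)
})

test_that("dance-level geocoding uses circular mean and duration summary", {
  s <- test_site()
  ph <- make_phases(3, 4, angle = 45, frames = 36)
  dn <- phases_to_dances(ph, s$fps)
  cal <- calibration_model(380)
  ep <- geocode_dances(dn, s, cal)
  expect_equal(nrow(ep), 3L)
  expect_true(all(ep$kind == "dance"))
  expect_equal(ep$distance_m, rep(380 * 0.6, 3))
  sol <- solar_position(dn$timestamp_utc, s$lat_deg, s$lon_deg)
  expect_equal(ep$bearing_deg, wrap_degrees(sol$azimuth_deg + 45))
})

test_that("geocoding warns when records are timestamped after dark", {
  s <- test_site()
  ph <- make_phases(1, 2, t0 = "2022-06-21T23:30:00Z")
  expect_warning(geocode_phases(ph, s, calibration_model(380)),
                 "below the horizon")
})
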