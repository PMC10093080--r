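test_that("simulation is bit-reproducible and respects phase-count bounds", {
  cfg <- sim_config(seed = 17)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$phases, b$phases)
  expect_identical(a$truth$dances, b$truth$dances)

  n <- nrow(a$phases)
  expect_gte(n, 141 * 8)
  expect_lte(n, 141 * 14)
  expect_equal(length(unique(a$phases$dance_id)), 141L)

  # different seed, different draws
  c <- simulate_session(sim_config(seed = 18))
  expect_false(identical(a$phases$angle_deg, c$phases$angle_deg))
})

test_that("simulated durations carry the configured noise scale", {
  cfg <- sim_config(n_dances = 120, phases_per_dance = c(9, 9), seed = 23)
  sim <- simulate_session(cfg)
  expect_gte(nrow(sim$phases), 1000)
  durs <- duration_from_frames(sim$phases$frame_start, sim$phases$frame_end,
                               cfg$fps)
  expect_lt(abs(sd(durs) - 0.14), 0.05)
  expect_lt(abs(mean(durs) - 230 / 380), 0.05)
})

test_that("with quantization as the only noise every endpoint hugs the feeder", {
  cfg <- sim_config(duration_sd_s = 0, angle_sd_deg = 0, n_dances = 30,
                    seed = 5)
  sim <- simulate_session(cfg)
  ep <- geocode_phases(sim$phases, cfg$site, calibration_model(cfg$v_true))
  feeder <- project_endpoint(cfg$site, 90, 230)
  d <- geosphere::distHaversine(cbind(ep$lon_deg, ep$lat_deg),
                             c(feeder$lon_deg, feeder$lat_deg), r = 6371000)
  ring <- ring_spacing(cfg$v_true, cfg$fps)$spacing_m
  expect_true(all(d <= ring + 0.5))  # half-frame rounding + azimuth drift
})

test_that("an over-dispersed duration model is rejected as a configuration error", {
  # a feeder so close that most duration draws would truncate at 1/fps
  expect_error(sim_config(feeder_distance_m = 1, duration_sd_s = 0.14),
               class = "wagglemap_config_error")
  expect_error(sim_config(n_dances = 0), class = "wagglemap_config_error")
  expect_error(sim_config(phases_per_dance = c(5, 2)),
               class = "wagglemap_config_error")
})

test_that("calibration error shrinks as duration noise is removed", {
  errs <- sapply(c(0.14, 0.07, 0.02, 0), function(sdv) {
    cfg <- sim_config(duration_sd_s = sdv, seed = 41)
    sim <- simulate_session(cfg)
    rr <- recovery_report(sim$phases, cfg$site,
                          list(bearing_deg = 90, distance_m = 230),
                          calibration_mode = "self", v_true = 380,
                          map = FALSE)
    abs(rr$v_error_fraction)
  })
  # monotone apart from the quantization floor shared by the last steps
  expect_lte(errs[4], errs[1])
  expect_lte(errs[3], errs[1])
  expect_true(all(errs <= 0.10))
})

test_that("a dance's circular-mean angle converges to the true angle", {
  err_at <- function(k) {
    mean(sapply(1:10, function(s) {
      cfg <- sim_config(n_dances = 1, phases_per_dance = c(k, k),
                        seed = 1000 + s)
      sim <- simulate_session(cfg)
      dn <- phases_to_dances(sim$phases, cfg$site$fps)
      abs(angle_diff_deg(dn$mean_angle_deg, sim$truth$dances$true_angle_deg))
    }))
  }
  e_small <- err_at(4)
  e_big <- err_at(100)
  expect_lt(e_big, e_small)
  expect_lt(e_big, 4)
})

test_that("a written session round-trips through the phase CSV", {
  cfg <- sim_config(n_dances = 8, seed = 99)
  sim <- simulate_session(cfg)
  dir <- withr::local_tempdir()
  paths <- write_session(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_phases(paths["phases"])
  expect_equal(as.data.frame(back), as.data.frame(sim$phases))
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$v_true, 380)
  expect_equal(length(truth$dances), 8L)
})
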