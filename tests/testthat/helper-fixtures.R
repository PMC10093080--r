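# Small in-code fixtures shared across test files.

test_site <- function(fps = 60) {
  hive_site(46.15, -0.64, fps = fps, utc_offset_h = 2)
}

# n phases spread over n_dances ids; angles/durations configurable
make_phases <- function(n_dances = 3, per_dance = 4, angle = 90,
                        frames = 36, t0 = "2022-06-21T10:49:00Z") {
  n <- n_dances * per_dance
  start <- seq.int(0, by = 100, length.out = n)
  waggle_phases(
    dance_id = rep(sprintf("d%02d", seq_len(n_dances)), each = per_dance),
    phase_index = rep(seq_len(per_dance) - 1L, times = n_dances),
    frame_start = start,
    frame_end = start + rep_len(frames, n),
    angle_deg = rep_len(angle, n),
    timestamp_utc = rep(t0, n)
  )
}

# endpoints laid out at given tangent-plane offsets from the hive
endpoints_at <- function(site, x, y, kind = "dance") {
  d <- sqrt(x^2 + y^2)
  b <- (atan2(x, y) * 180 / pi) %% 360
  b[d == 0] <- 0
  project_endpoint(site, b, d, source_id = as.character(seq_along(x)),
                   kind = kind)
}
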