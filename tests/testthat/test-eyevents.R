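test_that("pure jitter produces no events", {
  tr <- make_trace(jitter_sd = 0.05, seed = 4)
  expect_equal(nrow(detect_saccades(tr)), 0)
})

test_that("injected saccades are recovered with onset and amplitude", {
  tr <- make_trace(saccades = list(list(onset = 230, duration = 45,
                                        dx = 7.5, dy = 0)), seed = 6)
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 1)
  # the centered smoothing window can pull the crossing up to ~half a
  # window early on near-noiseless traces
  expect_lte(abs(ev$onset_ms - 230), 10)
  expect_lte(abs(ev$amplitude_deg - 7.5), 0.2)
  expect_gt(ev$offset_ms, ev$onset_ms)
})

test_that("two saccades 300 ms apart give two ordered events", {
  tr <- make_trace(n_ms = 900,
                   saccades = list(
                     list(onset = 200, duration = 45, dx = 7.5, dy = 0),
                     list(onset = 500, duration = 45, dx = -7.5, dy = 0)),
                   seed = 8)
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 2)
  expect_lt(ev$onset_ms[1], ev$onset_ms[2])
  expect_lte(abs(ev$onset_ms[1] - 200), 10)
  expect_lte(abs(ev$onset_ms[2] - 500), 10)
})

test_that("detection is translation invariant and time-shift equivariant", {
  tr <- make_trace(saccades = list(list(onset = 250, duration = 45,
                                        dx = 0, dy = -7.5)), seed = 10)
  ev <- detect_saccades(tr)
  shifted <- tr
  shifted$x_deg <- shifted$x_deg + 3.2
  shifted$y_deg <- shifted$y_deg - 1.7
  ev2 <- detect_saccades(shifted)
  expect_equal(ev2$onset_ms, ev$onset_ms)
  expect_equal(ev2$amplitude_deg, ev$amplitude_deg, tolerance = 1e-12)

  lagged <- tr
  lagged$t_ms <- lagged$t_ms + 1000
  ev3 <- detect_saccades(lagged)
  expect_equal(ev3$onset_ms, ev$onset_ms + 1000)
})

test_that("detector input validation catches short and gappy traces", {
  tr <- make_trace(seed = 12)
  expect_error(detect_saccades(tr[1:30, ]), "too short")
  gap <- tr[-(100:150), ]
  expect_error(detect_saccades(gap), "non-uniform")
  rev_t <- tr
  rev_t$t_ms[5] <- rev_t$t_ms[4]
  expect_error(detect_saccades(rev_t), "increasing")
})

make_record <- function(block_type = "saccade", cued = "right") {
  tibble::tibble(block_type = block_type, cued_location = cued,
                 cue_onset_ms = 0, stim_onset_ms = 140, stim_offset_ms = 170)
}

make_event <- function(onset, endpoint_x = 7.5, endpoint_y = 0) {
  tibble::tibble(onset_ms = onset, offset_ms = onset + 45,
                 duration_ms = 45,
                 amplitude_deg = sqrt(endpoint_x^2 + endpoint_y^2),
                 peak_speed_deg_s = 300, onset_x_deg = 0, onset_y_deg = 0,
                 endpoint_x_deg = endpoint_x, endpoint_y_deg = endpoint_y)
}

test_that("gating applies the latency, landing and presaccadic rules in order", {
  cfg <- design_config()
  # too early
  v <- gate_trial(make_record(), make_event(100), cfg)
  expect_false(v$accepted); expect_equal(v$reason, "latency_short")
  # too late
  v <- gate_trial(make_record(), make_event(360), cfg)
  expect_equal(v$reason, "latency_long")
  # in-window latency, good landing, stimulus inside the presaccadic window
  v <- gate_trial(make_record(), make_event(250, 7.5 + 1.0, 0), cfg)
  expect_true(v$accepted)
  expect_equal(v$reason, "ok")
  expect_equal(v$latency_ms, 250)
  expect_equal(v$landing_error_deg, 1.0)
  # latency admissible but stimulus no longer presaccadic: 340 - 140 > 150
  v <- gate_trial(make_record(), make_event(340), cfg)
  expect_equal(v$reason, "stim_not_presaccadic")
  # saccade before stimulus offset
  v <- gate_trial(make_record(), make_event(160), cfg)
  expect_equal(v$reason, "early_saccade")
  # landing outside the window
  v <- gate_trial(make_record(), make_event(250, 7.5 + 3, 0), cfg)
  expect_equal(v$reason, "landing_out")
  # no saccade at all
  v <- gate_trial(make_record(), presacc:::empty_events(), cfg)
  expect_equal(v$reason, "no_saccade")
})

test_that("fixation trials are gated on the fixation window and events", {
  cfg <- design_config()
  quiet <- make_trace(jitter_sd = 0.02, seed = 14)
  v <- gate_trial(make_record("fixation", NA), presacc:::empty_events(), cfg,
                  trace = quiet)
  expect_true(v$accepted)

  wandering <- quiet
  wandering$x_deg <- wandering$x_deg + seq(0, 3, length.out = nrow(wandering))
  v <- gate_trial(make_record("fixation", NA), presacc:::empty_events(), cfg,
                  trace = wandering)
  expect_equal(v$reason, "fixation_break")

  v <- gate_trial(make_record("fixation", NA), make_event(250), cfg,
                  trace = quiet)
  expect_equal(v$reason, "fixation_break")
})

test_that("verdicts are deterministic for identical inputs", {
  cfg <- design_config()
  v1 <- gate_trial(make_record(), make_event(250), cfg)
  v2 <- gate_trial(make_record(), make_event(250), cfg)
  expect_identical(v1, v2)
})

test_that("eye-parameter summaries average within then across participants", {
  set.seed(16)
  mk <- function(pp, dir, lat, n = 30) {
    target <- presacc:::location_xy(dir, 7.5)
    tibble::tibble(participant = pp, direction = dir,
                   latency_ms = stats::rnorm(n, lat, 5),
                   amplitude_deg = stats::rnorm(n, 7.5, 0.2),
                   landing_error_deg = abs(stats::rnorm(n, 0.7, 0.2)),
                   endpoint_x_deg = target[1] + stats::rnorm(n, 0, 0.4),
                   endpoint_y_deg = target[2] + stats::rnorm(n, 0, 0.4))
  }
  trials <- dplyr::bind_rows(
    purrr::map_dfr(1:3, function(p) dplyr::bind_rows(
      mk(p, "left", 240), mk(p, "right", 240), mk(p, "upper", 235),
      mk(p, "lower", 265))))
  out <- summarize_eye_params(trials)
  lat <- out$summary$latency_ms
  names(lat) <- as.character(out$summary$direction)
  expect_gt(lat[["lower"]], max(lat[c("left", "right", "upper")]))
  # map normalization: per-direction group map has maximum <= 1 and > 0
  peaks <- out$endpoint_maps |>
    dplyr::group_by(direction) |>
    dplyr::summarise(m = max(density))
  expect_true(all(peaks$m <= 1 + 1e-12))
  expect_true(all(peaks$m > 0))
})

test_that("endpoints at the target center collapse to the central cell", {
  trials <- tibble::tibble(
    participant = 1, direction = "right", latency_ms = 250,
    amplitude_deg = 7.5, landing_error_deg = 0,
    endpoint_x_deg = 7.5, endpoint_y_deg = 0)[rep(1, 10), ]
  out <- summarize_eye_params(trials)
  expect_equal(out$summary$landing_error_deg[
    out$summary$direction == "right"], 0)
  m <- out$endpoint_maps
  hot <- m[m$density == max(m$density), ]
  expect_true(all(abs(hot$dx_deg) <= 0.25 & abs(hot$dy_deg) <= 0.25))
  expect_equal(max(m$density), 1)
  # missing directions are flagged, not an error
  expect_true(out$summary$missing[out$summary$direction == "left"])
})
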