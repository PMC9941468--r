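test_that("the default design yields the canonical trial counts", {
  slots <- make_design(design_config(), seed = 1)
  expect_equal(nrow(slots), 1920)
  expect_equal(dplyr::n_distinct(slots$staircase_id), 48)
  counts <- dplyr::count(slots, condition)
  expect_equal(counts$n[counts$condition == "valid"], 640)
  expect_equal(counts$n[counts$condition == "invalid"], 640)
  expect_equal(counts$n[counts$condition == "baseline"], 640)
  expect_equal(sum(slots$block_type == "fixation"), 640)
  expect_equal(sum(slots$block_type == "saccade"), 1280)
  # each condition x stimulus-location cell gets staircases x trials slots
  cell <- dplyr::count(slots, condition, stim_location)
  expect_true(all(cell$n == 160))
  # every staircase id appears exactly 40 times
  expect_true(all(table(slots$staircase_id) == 40))
  # invalid trials are cued away from the stimulus
  inv <- slots[slots$condition == "invalid", ]
  expect_true(all(inv$cued_location != inv$stim_location))
  expect_true(all(slots$cued_location[slots$condition == "valid"] ==
                    slots$stim_location[slots$condition == "valid"]))
})

test_that("a minimal 12-slot design and config errors behave as specified", {
  cfg <- design_config(n_fixation_blocks = 1, trials_per_fixation_block = 4,
                       n_saccade_blocks = 1, trials_per_saccade_block = 8,
                       staircases_per_cell = 1, trials_per_staircase = 1)
  slots <- make_design(cfg, seed = 3)
  expect_equal(nrow(slots), 12)
  expect_equal(nrow(dplyr::distinct(slots, condition, stim_location)), 12)

  expect_error(design_config(trials_per_fixation_block = 100),
               "n_fixation_blocks")
  expect_error(design_config(trials_per_saccade_block = 100),
               "n_saccade_blocks")
  expect_error(design_config(stim_duration_ms = -1), "positive")
})

test_that("design generation is deterministic given the seed", {
  a <- make_design(design_config(), seed = 9)
  b <- make_design(design_config(), seed = 9)
  expect_identical(a, b)
  c <- make_design(design_config(), seed = 10)
  expect_false(identical(a, c))
})

test_that("simulated responses follow the observer's psychometric function", {
  obs <- observer_params(lapse_rate = 0)
  th <- obs$baseline_threshold_cpd[["left"]]
  set.seed(13)
  acc <- mean(replicate(4000, simulate_response(th, "baseline", "left", obs)))
  expect_equal(acc, 0.75, tolerance = 0.025)
  acc_hi <- mean(replicate(1000, simulate_response(1e6, "baseline", "left", obs)))
  expect_equal(acc_hi, 0.5, tolerance = 0.05)
  expect_error(simulate_response(-2, "baseline", "left", obs), "positive")
})

test_that("a valid cue raises accuracy near threshold (multiplier > 1)", {
  obs <- observer_params(lapse_rate = 0)
  th <- obs$baseline_threshold_cpd[["left"]]
  # analytic check of the effective-parameter contract ...
  expect_gt(logistic_prob(th, effective_params(obs, "valid", "left")),
            logistic_prob(th, effective_params(obs, "baseline", "left")))
  expect_lt(logistic_prob(th, effective_params(obs, "invalid", "left")),
            logistic_prob(th, effective_params(obs, "baseline", "left")))
  # ... and by simulation at the same stimulus
  set.seed(17)
  n <- 20000
  acc_v <- mean(replicate(n, simulate_response(th, "valid", "left", obs)))
  acc_b <- mean(replicate(n, simulate_response(th, "baseline", "left", obs)))
  expect_gt(acc_v, acc_b)
})

test_that("fixation traces carry no saccade; saccade traces exactly one", {
  cfg <- design_config()
  gz <- gaze_sim_params()
  set.seed(19)
  fx <- simulate_trace(list(block_type = "fixation", cued_location = NA),
                       gz, cfg)
  expect_equal(fx$annotation$n_saccades, 0L)
  expect_true(all(abs(fx$trace$x_deg) < 1))
  expect_equal(fx$trace$t_ms[1], 0)
  expect_equal(max(fx$trace$t_ms), 620)

  sc <- simulate_trace(list(block_type = "saccade", cued_location = "right"),
                       gz, cfg)
  expect_equal(sc$annotation$n_saccades, 1L)
  expect_gte(sc$annotation$true_latency_ms, 150)
  expect_lte(sc$annotation$true_latency_ms, 350)
  expect_gt(sc$annotation$endpoint_x_deg, 5)

  expect_error(
    simulate_trace(list(block_type = "fixation", cued_location = NA), gz,
                   design_config(sampling_rate_hz = 100)),
    "250 Hz")
})

test_that("annotated onsets are recovered by the detector within 5 ms", {
  cfg <- design_config()
  gz <- gaze_sim_params()
  set.seed(23)
  for (i in 1:10) {
    loc <- sample(c("left", "right", "upper", "lower"), 1)
    tr <- simulate_trace(list(block_type = "saccade", cued_location = loc),
                         gz, cfg)
    ev <- detect_saccades(tr$trace)
    expect_equal(nrow(ev), 1)
    expect_lte(abs(ev$onset_ms - tr$annotation$true_onset_ms), 5)
  }
})

test_that("downward saccades are slower by construction", {
  cfg <- design_config()
  gz <- gaze_sim_params()
  set.seed(29)
  lat <- function(loc) replicate(200, simulate_trace(
    list(block_type = "saccade", cued_location = loc), gz,
    cfg)$annotation$true_latency_ms)
  expect_gt(mean(lat("lower")), mean(lat("upper")))
})

test_that("simulated speed clears the detectability margin over jitter", {
  cfg <- design_config()
  gz <- gaze_sim_params()
  set.seed(31)
  smoothed_speed <- function(trace) {
    n <- nrow(trace); dt <- 0.001
    vx <- c(0, (trace$x_deg[-(1:2)] - trace$x_deg[1:(n - 2)]) / (2 * dt), 0)
    vy <- c(0, (trace$y_deg[-(1:2)] - trace$y_deg[1:(n - 2)]) / (2 * dt), 0)
    sqrt(as.numeric(stats::filter(vx, rep(1 / 20, 20), sides = 2,
                                  circular = TRUE))^2 +
           as.numeric(stats::filter(vy, rep(1 / 20, 20), sides = 2,
                                    circular = TRUE))^2)
  }
  fix_speed <- unlist(replicate(20, smoothed_speed(
    simulate_trace(list(block_type = "fixation", cued_location = NA),
                   gz, cfg)$trace), simplify = FALSE))
  peak <- max(smoothed_speed(
    simulate_trace(list(block_type = "saccade", cued_location = "left"),
                   gz, cfg)$trace))
  expect_gt(peak, 10 * stats::quantile(fix_speed, 0.99))
})

test_that("a session completes every staircase with its full trial count", {
  s <- simulate_session(small_design(), seed = 101, gaze = gaze_sim_params(),
                        store_gaze = TRUE)
  acc <- s$trials[s$trials$accepted_online, ]
  expect_true(all(table(acc$staircase_id) == 8))
  expect_equal(length(s$staircases), 12)
  expect_true(all(s$staircase_estimates$threshold_cpd > 0))
  # bookkeeping: every attempt is either accepted or carries a reason
  expect_true(all(s$trials$reject_reason[!s$trials$accepted_online] != "ok"))
  expect_equal(sum(s$trials$accepted_online) +
                 sum(!s$trials$accepted_online), nrow(s$trials))
  # gaze store covers every attempt
  expect_setequal(unique(s$gaze$trial_uid), s$trials$trial_uid)
})

test_that("noise-free gaze produces zero online rejections", {
  gz <- gaze_sim_params(latency_sd_ms = 0, landing_sd_deg = 0,
                        fixation_jitter_sd_deg = 0,
                        latency_mean_ms = c(left = 250, right = 250,
                                            upper = 250, lower = 250))
  s <- simulate_session(small_design(), seed = 5, gaze = gz,
                        obs = observer_params(lapse_rate = 0),
                        store_gaze = FALSE)
  expect_true(all(s$trials$accepted_online))
})

test_that("sloppy landings are re-queued without changing accepted counts", {
  gz <- gaze_sim_params(landing_sd_deg = 3.0)
  s <- simulate_session(small_design(), seed = 7, gaze = gz,
                        store_gaze = FALSE)
  expect_gt(sum(s$trials$reject_reason == "landing_out"), 0)
  acc <- s$trials[s$trials$accepted_online, ]
  expect_true(all(table(acc$staircase_id) == 8))
})

test_that("sessions are reproducible given the seed", {
  a <- simulate_session(small_design(), seed = 77, gaze = NULL)
  b <- simulate_session(small_design(), seed = 77, gaze = NULL)
  expect_identical(a$trials, b$trials)
  expect_identical(a$staircase_estimates, b$staircase_estimates)
})
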