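# Online gating from ground-truth annotations. The online rules mirror the
# offline gate but are evaluated against the simulator's own event
# annotations, never the detector -- generation and inference stay separate.
online_verdict <- function(slot, annotation, trace, config) {
  stim_offset <- config$cue_to_stim_ms + config$stim_duration_ms
  if (slot$block_type == "fixation") {
    r <- sqrt(trace$x_deg^2 + trace$y_deg^2)
    if (any(r > config$fixation_window_deg)) return("fixation_break")
    return("ok")
  }
  onset <- annotation$true_onset_ms
  if (is.na(onset)) return("no_saccade")
  if (onset < config$latency_min_ms) return("latency_short")
  if (onset > config$latency_max_ms) return("latency_long")
  target <- location_xy(slot$cued_location, config$eccentricity)
  landing <- sqrt((annotation$endpoint_x_deg - target[1])^2 +
                    (annotation$endpoint_y_deg - target[2])^2)
  if (landing > config$landing_window_deg) return("landing_out")
  if (onset < stim_offset) return("early_saccade")
  "ok"
}

#' Simulate one complete experimental session
#'
#' Runs the closed loop between the trial schedule, the adaptive
#' staircases, the synthetic observer, and (optionally) the gaze
#' simulator. The session opens with an initial fixation titration -- one
#' adaptive procedure per location from a common wide starting
#' configuration -- whose thresholds calibrate the per-meridian staircase
#' grids ([calibrate_start()]). Each trial's spatial frequency is then
#' requested from its staircase, the gaze trace simulated and gated
#' online (against the ground-truth annotations), and the observer's
#' response fed back only for accepted trials. Rejected trials are
#' re-queued at the end of their block, so every staircase finishes with
#' its full complement of accepted trials.
#'
#' @param config A [design_config()].
#' @param obs An [observer_params()].
#' @param gaze A [gaze_sim_params()], or `NULL` to skip gaze synthesis
#'   entirely (response-only mode: every trial is accepted online).
#' @param seed Integer seed; the session is fully deterministic given it.
#' @param participant Participant label recorded in the outputs.
#' @param staircase_opts Named list of overrides passed to
#'   [staircase_config()] for the main procedures (e.g. `placement_rule`).
#' @param initial_thresholds Optional named vector (left/right/upper/lower,
#'   cpd) to use for calibration instead of simulating the initial block.
#' @param store_gaze Keep the full traces in the returned object (they are
#'   large); annotations are always kept.
#' @param max_attempts_factor Abort with an error if a block needs more
#'   than `max_attempts_factor` times its nominal trial count.
#' @return An `acuity_session` list: `trials` (the trial table, one row per
#'   attempt, with `accepted_online` and `reject_reason`), `gaze` (long
#'   tibble of traces or `NULL`), `annotations`, `staircase_estimates`
#'   (per-procedure thresholds via [estimate_threshold()]),
#'   `staircases` (final states), `initial_thresholds`, `calibration`,
#'   and the parameter objects.
#' @examples
#' \donttest{
#' cfg <- design_config(n_fixation_blocks = 1, trials_per_fixation_block = 32,
#'                      n_saccade_blocks = 1, trials_per_saccade_block = 64,
#'                      staircases_per_cell = 1, trials_per_staircase = 8)
#' s <- simulate_session(cfg, seed = 1, gaze = NULL)
#' dplyr::count(s$trials, condition)
#' }
#' @export
simulate_session <- function(config = design_config(),
                             obs = observer_params(),
                             gaze = gaze_sim_params(),
                             seed = 1,
                             participant = 1L,
                             staircase_opts = list(),
                             initial_thresholds = NULL,
                             store_gaze = TRUE,
                             max_attempts_factor = 5) {
  stopifnot(inherits(config, "design_config"), inherits(obs, "observer_params"))
  set.seed(seed)

  # -- initial fixation titration: common wide grid for all locations
  if (is.null(initial_thresholds)) {
    init_cfg <- do.call(staircase_config, utils::modifyList(
      list(lower_limit_log10 = log10(2),
           start_log10 = log10(2) + 0.5,
           n_trials = config$trials_per_staircase),
      staircase_opts))
    initial_thresholds <- vapply(config$locations, function(loc) {
      st <- run_staircase(init_cfg, function(sf)
        simulate_response(sf, "baseline", loc, obs))
      estimate_threshold(st)
    }, numeric(1))
  }
  calibration <- calibrate_start(initial_thresholds)

  meridian_of <- c(left = "horizontal", right = "horizontal",
                   upper = "vertical", lower = "vertical")
  stair_cfgs <- lapply(stats::setNames(config$locations, config$locations),
    function(loc) {
      lim <- calibration$lower_limit_log10[
        calibration$meridian == meridian_of[[loc]]]
      do.call(staircase_config, utils::modifyList(
        list(lower_limit_log10 = lim, start_log10 = lim + 0.5,
             prior_sd_log10 = 0.3,
             n_trials = config$trials_per_staircase),
        staircase_opts))
    })

  slots <- make_design(config, seed = seed + 1L)
  ids <- unique(slots$staircase_id)
  bank <- lapply(stats::setNames(ids, ids), function(id) {
    loc <- strsplit(id, "_")[[1]][2]
    staircase_init(stair_cfgs[[loc]])
  })

  simulate_gaze <- !is.null(gaze)
  cap <- as.integer(ceiling(nrow(slots) * max_attempts_factor))
  rec <- list(slot_row = integer(cap), block = integer(cap),
              trial = integer(cap), uid = character(cap),
              sf = numeric(cap), correct = rep(NA, cap),
              accepted = logical(cap), reason = character(cap))
  gaze_rows <- list()
  annot_rows <- list()
  row_i <- 0L

  for (b in unique(slots$block)) {
    queue <- which(slots$block == b)
    nominal <- length(queue)
    attempts <- 0L
    trial_in_block <- 0L
    while (length(queue) > 0) {
      attempts <- attempts + 1L
      if (attempts > max_attempts_factor * nominal)
        stop("re-queue livelock: block ", b, " exceeded ",
             max_attempts_factor * nominal, " attempts", call. = FALSE)
      k <- queue[1]
      queue <- queue[-1]
      trial_in_block <- trial_in_block + 1L
      row_i <- row_i + 1L
      uid <- sprintf("p%02d_b%02d_t%04d", participant, b, trial_in_block)
      id <- slots$staircase_id[k]

      sf <- select_stimulus(bank[[id]])

      if (simulate_gaze) {
        slot <- list(block_type = slots$block_type[k],
                     cued_location = slots$cued_location[k])
        tr <- simulate_trace(slot, gaze, config)
        reason <- online_verdict(slot, tr$annotation, tr$trace, config)
        tr$annotation$trial_uid <- uid
        annot_rows[[row_i]] <- tr$annotation
        if (store_gaze) {
          tr$trace$trial_uid <- uid
          gaze_rows[[row_i]] <- tr$trace
        }
      } else {
        reason <- "ok"
      }
      accepted <- reason == "ok"
      if (accepted) {
        correct <- simulate_response(sf, slots$condition[k],
                                     slots$stim_location[k], obs)
        bank[[id]] <- update_posterior(bank[[id]], sf, correct)
        rec$correct[row_i] <- correct
      } else {
        queue <- c(queue, k)  # repeat at end of block
      }
      rec$slot_row[row_i] <- k
      rec$block[row_i] <- b
      rec$trial[row_i] <- trial_in_block
      rec$uid[row_i] <- uid
      rec$sf[row_i] <- sf
      rec$accepted[row_i] <- accepted
      rec$reason[row_i] <- reason
    }
  }

  keep <- seq_len(row_i)
  sr <- rec$slot_row[keep]
  trials <- tibble::tibble(
    participant = participant, trial_uid = rec$uid[keep],
    block = rec$block[keep], block_type = slots$block_type[sr],
    trial = rec$trial[keep], condition = slots$condition[sr],
    cued_location = slots$cued_location[sr],
    stim_location = slots$stim_location[sr],
    staircase_id = slots$staircase_id[sr],
    sf_cpd = rec$sf[keep], correct = rec$correct[keep],
    cue_onset_ms = 0, stim_onset_ms = config$cue_to_stim_ms,
    stim_offset_ms = config$cue_to_stim_ms + config$stim_duration_ms,
    accepted_online = rec$accepted[keep], reject_reason = rec$reason[keep])

  estimates <- purrr::imap_dfr(bank, function(st, id) {
    parts <- strsplit(id, "_")[[1]]
    tibble::tibble(staircase_id = id, condition = parts[1],
                   location = parts[2], rep = as.integer(parts[3]),
                   threshold_cpd = estimate_threshold(st))
  })

  structure(
    list(trials = trials,
         gaze = if (simulate_gaze && store_gaze) dplyr::bind_rows(gaze_rows) else NULL,
         annotations = if (simulate_gaze) dplyr::bind_rows(annot_rows) else NULL,
         staircase_estimates = estimates,
         staircases = bank,
         initial_thresholds = initial_thresholds,
         calibration = calibration,
         config = config, obs = obs, gaze_params = gaze,
         participant = participant, seed = seed),
    class = "acuity_session"
  )
}

#' @export
print.acuity_session <- function(x, ...) {
  acc <- sum(x$trials$accepted_online)
  cat(sprintf(
    "Simulated session (participant %s, seed %d): %d trial attempts, %d accepted, %d staircases\n",
    x$participant, x$seed, nrow(x$trials), acc, length(x$staircases)))
  invisible(x)
}
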