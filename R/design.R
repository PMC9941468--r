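LOCATIONS <- c("left", "right", "upper", "lower")
CONDITIONS <- c("valid", "baseline", "invalid")

location_xy <- function(location, eccentricity) {
  dx <- c(left = -1, right = 1, upper = 0, lower = 0)
  dy <- c(left = 0, right = 0, upper = 1, lower = -1)
  cbind(x = dx[location] * eccentricity, y = dy[location] * eccentricity)
}

#' Experimental design configuration
#'
#' Holds the structural constants of one session: four stimulus locations
#' at iso-eccentricity on the cardinal meridians, three attentional
#' conditions (`valid` at the saccade target, `invalid` at a non-target,
#' `baseline` during fixation), block structure, per-cell staircase counts,
#' event timing, and the gaze-contingent acceptance windows.
#'
#' The defaults give the canonical session: 4 fixation blocks of 160
#' trials plus 4 eye-movement blocks of 320 trials (1920 trials: 640
#' fixation, 640 valid, 640 invalid), feeding 48 adaptive procedures
#' (3 conditions x 4 locations x 4 replicates) of 40 trials each. The cue
#' precedes the stimulus by 140 ms, the stimulus lasts 30 ms, and the
#' response cue follows stimulus offset by 450 ms. Fixation and saccade
#' landing must stay within a 2.25 degree radius; saccade latencies must
#' fall in [150, 350] ms and the stimulus must end within the 150 ms
#' presaccadic window.
#'
#' @param eccentricity Stimulus eccentricity in degrees.
#' @param n_fixation_blocks,trials_per_fixation_block Fixation-block layout.
#' @param n_saccade_blocks,trials_per_saccade_block Eye-movement-block layout.
#' @param staircases_per_cell Replicate adaptive procedures per
#'   condition-location cell.
#' @param trials_per_staircase Trials absorbed by each procedure.
#' @param cue_to_stim_ms,stim_duration_ms,response_cue_delay_ms Event timing.
#' @param fixation_window_deg,landing_window_deg Gaze windows (radius, deg).
#' @param latency_min_ms,latency_max_ms Admissible saccade latencies.
#' @param presacc_window_ms Presaccadic stimulus window.
#' @param sampling_rate_hz Eye-tracker sampling rate.
#' @return A `design_config` object (named list).
#' @export
design_config <- function(eccentricity = 7.5,
                          n_fixation_blocks = 4,
                          trials_per_fixation_block = 160,
                          n_saccade_blocks = 4,
                          trials_per_saccade_block = 320,
                          staircases_per_cell = 4,
                          trials_per_staircase = 40,
                          cue_to_stim_ms = 140,
                          stim_duration_ms = 30,
                          response_cue_delay_ms = 450,
                          fixation_window_deg = 2.25,
                          landing_window_deg = 2.25,
                          latency_min_ms = 150,
                          latency_max_ms = 350,
                          presacc_window_ms = 150,
                          sampling_rate_hz = 1000) {
  cfg <- as.list(environment())
  num <- unlist(cfg)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all design quantities must be strictly positive", call. = FALSE)
  fix_total <- n_fixation_blocks * trials_per_fixation_block
  cell_total <- length(LOCATIONS) * staircases_per_cell * trials_per_staircase
  if (fix_total != cell_total)
    stop("design inconsistency: n_fixation_blocks * trials_per_fixation_block (",
         fix_total, ") must equal |locations| * staircases_per_cell * ",
         "trials_per_staircase (", cell_total, ")", call. = FALSE)
  sac_total <- n_saccade_blocks * trials_per_saccade_block
  if (sac_total != 2 * cell_total)
    stop("design inconsistency: n_saccade_blocks * trials_per_saccade_block (",
         sac_total, ") must equal 2 * |locations| * staircases_per_cell * ",
         "trials_per_staircase (", 2 * cell_total, ")", call. = FALSE)
  if (trials_per_staircase %% n_fixation_blocks != 0 ||
      trials_per_staircase %% n_saccade_blocks != 0)
    stop("design inconsistency: trials_per_staircase must divide evenly ",
         "across blocks", call. = FALSE)
  cfg$locations <- LOCATIONS
  cfg$conditions <- CONDITIONS
  structure(cfg, class = "design_config")
}

#' Lay out the trial schedule of one session
#'
#' Expands a [design_config()] into the ordered list of trial slots. Every
#' condition-by-stimulus-location cell receives exactly
#' `staircases_per_cell * trials_per_staircase` slots, spread evenly over
#' blocks of its type and shuffled within block. In eye-movement blocks
#' valid and invalid trials are balanced 1:1; on invalid trials the cue
#' (saccade target) is drawn uniformly from the three locations other than
#' the stimulus location, so the stimulus is equally often at each
#' non-target position. Fully deterministic given `seed`.
#'
#' @param config A [design_config()].
#' @param seed Integer seed controlling block order, within-block shuffles,
#'   and invalid-trial cue draws.
#' @return A tibble of slots: `block`, `block_type`, `trial`, `condition`,
#'   `cued_location`, `stim_location`, `staircase_id`.
#' @examples
#' slots <- make_design(design_config(), seed = 1)
#' nrow(slots)                       # 1920
#' dplyr::n_distinct(slots$staircase_id) # 48
#' @export
make_design <- function(config = design_config(), seed = 1) {
  stopifnot(inherits(config, "design_config"))
  set.seed(seed)
  per_block_fix <- config$trials_per_staircase / config$n_fixation_blocks
  per_block_sac <- config$trials_per_staircase / config$n_saccade_blocks

  staircase_id <- function(cond, loc, rep) paste(cond, loc, rep, sep = "_")
  reps <- seq_len(config$staircases_per_cell)

  fix_block <- function() {
    g <- expand.grid(rep = reps, stim_location = config$locations,
                     stringsAsFactors = FALSE)
    g <- g[rep(seq_len(nrow(g)), each = per_block_fix), ]
    tibble::tibble(
      condition = "baseline",
      cued_location = NA_character_,
      stim_location = g$stim_location,
      staircase_id = staircase_id("baseline", g$stim_location, g$rep))
  }
  sac_block <- function() {
    g <- expand.grid(rep = reps, stim_location = config$locations,
                     condition = c("valid", "invalid"),
                     stringsAsFactors = FALSE)
    g <- g[rep(seq_len(nrow(g)), each = per_block_sac), ]
    cued <- ifelse(g$condition == "valid", g$stim_location, NA)
    inv <- which(g$condition == "invalid")
    cued[inv] <- vapply(g$stim_location[inv], function(loc)
      sample(setdiff(config$locations, loc), 1), character(1))
    tibble::tibble(
      condition = g$condition,
      cued_location = cued,
      stim_location = g$stim_location,
      staircase_id = staircase_id(g$condition, g$stim_location, g$rep))
  }

  block_types <- sample(c(rep("fixation", config$n_fixation_blocks),
                          rep("saccade", config$n_saccade_blocks)))
  blocks <- purrr::imap(block_types, function(type, b) {
    slots <- if (type == "fixation") fix_block() else sac_block()
    slots <- slots[sample(nrow(slots)), ]
    dplyr::mutate(slots, block = b, block_type = type,
                  trial = dplyr::row_number(), .before = 1)
  })
  dplyr::bind_rows(blocks)
}

#' Ground-truth observer parameters
#'
#' The simulated observer answers each 2AFC trial by a Bernoulli draw from
#' the logistic acuity model with an *effective* threshold equal to the
#' location's baseline threshold scaled by the condition multiplier:
#' above 1 for `valid` (presaccadic benefit at the saccade target), below 1
#' for `invalid` (cost at non-target locations), 1 for `baseline`.
#'
#' Default baseline thresholds encode the canonical performance-field
#' asymmetries -- horizontal locations above vertical (HVA) and the lower
#' location above the upper (VMA) -- at the operating point of the
#' experiment this package emulates; the default multipliers correspond to
#' a ~2.5% benefit and ~5.9% cost.
#'
#' @param baseline_threshold_cpd Named numeric (left/right/upper/lower),
#'   baseline 75%-correct thresholds in cpd.
#' @param slope Logistic slope per log10-SF unit.
#' @param lapse_rate Observer lapse rate in `[0, 0.1]`.
#' @param guess_rate 2AFC guess rate, fixed 0.5.
#' @param valid_multiplier,invalid_multiplier Condition scalings of the
#'   baseline threshold.
#' @return An `observer_params` object.
#' @export
observer_params <- function(baseline_threshold_cpd = c(left = 9.458,
                                                       right = 9.609,
                                                       upper = 6.883,
                                                       lower = 7.817),
                            slope = 15,
                            lapse_rate = 0.01,
                            guess_rate = 0.5,
                            valid_multiplier = 1.025,
                            invalid_multiplier = 0.941) {
  if (!all(LOCATIONS %in% names(baseline_threshold_cpd)))
    stop("`baseline_threshold_cpd` must be named left, right, upper, lower",
         call. = FALSE)
  th <- baseline_threshold_cpd[LOCATIONS]
  if (any(th <= 0)) stop("baseline thresholds must be positive", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate > 0.1)
    stop("`lapse_rate` must lie in [0, 0.1]", call. = FALSE)
  if (guess_rate != 0.5)
    stop("`guess_rate` is fixed at 0.5 for 2AFC", call. = FALSE)
  structure(
    list(baseline_threshold_cpd = th, slope = slope, lapse_rate = lapse_rate,
         guess_rate = guess_rate, valid_multiplier = valid_multiplier,
         invalid_multiplier = invalid_multiplier),
    class = "observer_params"
  )
}

condition_multiplier <- function(obs, condition) {
  switch(condition,
         valid = obs$valid_multiplier,
         baseline = 1,
         invalid = obs$invalid_multiplier,
         stop("unknown condition: ", condition, call. = FALSE))
}

#' Effective psychometric parameters of an observer in one cell
#'
#' @param obs An [observer_params()].
#' @param condition One of `"valid"`, `"baseline"`, `"invalid"`.
#' @param location One of `"left"`, `"right"`, `"upper"`, `"lower"`.
#' @return A [psy_params()] with the condition-scaled threshold.
#' @export
effective_params <- function(obs, condition, location) {
  stopifnot(inherits(obs, "observer_params"))
  psy_params(
    threshold_cpd = obs$baseline_threshold_cpd[[location]] *
      condition_multiplier(obs, condition),
    slope = obs$slope, guess_rate = obs$guess_rate,
    lapse_rate = obs$lapse_rate)
}

#' Simulate one 2AFC response
#'
#' Bernoulli draw from the observer's effective psychometric function
#' (uses the session RNG stream; wrap in [withr::with_seed()] or set the
#' seed for reproducibility).
#'
#' @param sf_cpd Presented spatial frequency (cpd, positive).
#' @param condition,location Trial cell.
#' @param obs An [observer_params()].
#' @return Logical: response correct?
#' @export
simulate_response <- function(sf_cpd, condition, location, obs) {
  if (!is.finite(sf_cpd) || sf_cpd <= 0)
    stop("`sf_cpd` must be positive", call. = FALSE)
  p <- logistic_prob(sf_cpd, effective_params(obs, condition, location))
  stats::runif(1) < p
}
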