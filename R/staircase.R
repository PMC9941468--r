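#' Calibrate staircase lower limits and starting values per meridian
#'
#' The adaptive procedures for each meridian are anchored to the initial
#' thresholds measured during fixation: the lowest admissible threshold is
#' 0.5 log10 spatial-frequency units below the mean of the two initial
#' thresholds on that meridian (left/right for horizontal, upper/lower for
#' vertical), and the starting stimulus sits 0.5 log10 units above the
#' limit, i.e. at the initial-threshold mean itself. All three attentional
#' conditions at a given location share the same calibration.
#'
#' @param initial_thresholds Named numeric vector of positive thresholds in
#'   cpd with names `left`, `right`, `upper`, `lower`.
#' @param offset_log10 Distance (log10 units) between the initial-threshold
#'   mean and the lower limit.
#' @return A tibble with one row per meridian: `meridian`,
#'   `lower_limit_log10`, `start_log10`, `start_cpd`.
#' @examples
#' calibrate_start(c(left = 9.458, right = 9.609, upper = 6.883, lower = 7.817))
#' @export
calibrate_start <- function(initial_thresholds, offset_log10 = 0.5) {
  need <- c("left", "right", "upper", "lower")
  if (!all(need %in% names(initial_thresholds)))
    stop("`initial_thresholds` must be named left, right, upper, lower",
         call. = FALSE)
  th <- initial_thresholds[need]
  if (any(!is.finite(th)) || any(th <= 0))
    stop("initial thresholds must be positive and finite", call. = FALSE)
  h <- mean(log10(th[c("left", "right")]))
  v <- mean(log10(th[c("upper", "lower")]))
  tibble::tibble(
    meridian = c("horizontal", "vertical"),
    lower_limit_log10 = c(h, v) - offset_log10,
    start_log10 = c(h, v),
    start_cpd = 10^c(h, v)
  )
}

#' Configure a Bayesian adaptive staircase
#'
#' Builds the discrete parameter grid, prior, and placement settings of one
#' adaptive titration procedure. The posterior lives on a threshold-by-slope
#' grid of 61 threshold points spanning 1.5 log10 cpd upward from the
#' calibrated lower limit. By default the slope is held fixed at a single
#' representative value (QUEST-style): marginalising over a broad slope
#' grid roughly doubles the threshold estimate's standard deviation in
#' 40-trial runs, because shallow-slope hypotheses are never ruled out by
#' near-threshold data and keep the posterior diffuse. Widen `n_slope` /
#' `slope_range` to marginalise instead. The prior over the grid is
#' uniform unless `prior_sd_log10` is set, in which case it is a Gaussian
#' in log10 threshold centered on the calibrated starting value -- the
#' principled use of the initial titration block that produced the
#' calibration. The procedure targets `target_performance` (75% for
#' 2AFC) over `n_trials` trials.
#'
#' Inside the engine the response likelihood carries a small fixed lapse
#' (`engine_lapse`, default 0.005) so that a single surprising response can
#' never zero out the posterior; threshold placement and reporting use the
#' lapse-free parameterisation, keeping the estimate exactly the
#' target-performance point.
#'
#' @param lower_limit_log10 Lowest admissible log10 threshold (from
#'   [calibrate_start()]).
#' @param span_log10 Width of the threshold grid in log10 units.
#' @param n_threshold,n_slope Grid resolutions.
#' @param slope_range Slope grid limits (log-spaced points); a degenerate
#'   range with `n_slope = 1` fixes the slope.
#' @param prior_sd_log10 If non-NULL, SD of a Gaussian prior on the log10
#'   threshold centered at `start_log10` (or the grid center when no start
#'   is given); NULL gives a uniform prior.
#' @param n_trials Trials per procedure (default 40).
#' @param target_performance Accuracy the procedure tracks (default 0.75).
#' @param placement_rule `"posterior-mean"` (default) places each trial at
#'   the target-performance point of the posterior-mean parameters;
#'   `"entropy-min"` picks the candidate stimulus minimising expected
#'   posterior entropy.
#' @param candidate_stimuli_log10 Candidate stimulus set (log10 cpd);
#'   defaults to the threshold grid. Placement is clamped to its range.
#' @param start_log10 Optional calibrated starting stimulus (log10 cpd)
#'   presented on the first trial, before the posterior carries any
#'   information; `NULL` falls back to the placement rule under the prior.
#' @param guess_rate,engine_lapse 2AFC asymptotes used in the engine
#'   likelihood.
#' @return A `staircase_config` object (named list).
#' @export
staircase_config <- function(lower_limit_log10,
                             span_log10 = 1.5,
                             n_threshold = 61,
                             n_slope = 1,
                             slope_range = c(15, 15),
                             n_trials = 40,
                             target_performance = 0.75,
                             placement_rule = c("posterior-mean", "entropy-min"),
                             candidate_stimuli_log10 = NULL,
                             start_log10 = NULL,
                             prior_sd_log10 = NULL,
                             guess_rate = 0.5,
                             engine_lapse = 0.005) {
  placement_rule <- match.arg(placement_rule)
  if (target_performance <= guess_rate || target_performance >= 1 - engine_lapse)
    stop("`target_performance` must lie strictly between guess rate and 1 - lapse",
         call. = FALSE)
  threshold_grid <- seq(lower_limit_log10, lower_limit_log10 + span_log10,
                        length.out = n_threshold)
  slope_grid <- if (n_slope == 1) mean(slope_range) else
    exp(seq(log(slope_range[1]), log(slope_range[2]), length.out = n_slope))
  if (is.null(candidate_stimuli_log10)) candidate_stimuli_log10 <- threshold_grid
  if (length(candidate_stimuli_log10) == 0)
    stop("empty candidate stimulus set", call. = FALSE)
  structure(
    list(threshold_grid = threshold_grid,
         slope_grid = slope_grid,
         n_trials = n_trials,
         target_performance = target_performance,
         placement_rule = placement_rule,
         candidate_stimuli_log10 = sort(candidate_stimuli_log10),
         start_log10 = start_log10,
         prior_sd_log10 = prior_sd_log10,
         guess_rate = guess_rate,
         engine_lapse = engine_lapse),
    class = "staircase_config"
  )
}

#' Initialise a staircase state
#'
#' @param config A [staircase_config()] object.
#' @param prior Optional matrix of prior mass (threshold grid in rows, slope
#'   grid in columns); defaults to uniform. Normalised internally.
#' @return A `staircase_state` object holding the posterior matrix, trial
#'   history, and the configuration.
#' @export
staircase_init <- function(config, prior = NULL) {
  stopifnot(inherits(config, "staircase_config"))
  nt <- length(config$threshold_grid); ns <- length(config$slope_grid)
  if (is.null(prior)) {
    if (is.null(config$prior_sd_log10)) {
      prior <- matrix(1, nt, ns)
    } else {
      center <- if (is.null(config$start_log10))
        mean(range(config$threshold_grid)) else config$start_log10
      w <- stats::dnorm(config$threshold_grid, center, config$prior_sd_log10)
      prior <- matrix(rep(w, ns), nt, ns)
    }
  }
  if (!all(dim(prior) == c(nt, ns)) || any(prior < 0) || sum(prior) <= 0)
    stop("`prior` must be a non-negative ", nt, "x", ns, " matrix", call. = FALSE)
  structure(
    list(posterior = prior / sum(prior),
         sf_history = rep(NA_real_, config$n_trials),
         correct_history = rep(NA, config$n_trials),
         trial_index = 0L,
         config = config),
    class = "staircase_state"
  )
}

# P(correct | sf, theta, beta) on the full grid, with engine lapse.
grid_likelihood <- function(sf_cpd, config) {
  u <- -log10(sf_cpd)
  # z = slope * (u - u_alpha) with u_alpha = -threshold_grid (log10 cpd);
  # threshold in rows, slope in columns
  z <- outer(u + config$threshold_grid, config$slope_grid)
  config$guess_rate +
    (1 - config$guess_rate - config$engine_lapse) * stats::plogis(z)
}

#' Bayes-update a staircase posterior with one trial
#'
#' Multiplies the posterior by the likelihood of the observed response
#' under the 2AFC logistic model at each grid point and renormalises;
#' the trial is appended to the history.
#'
#' @param state A `staircase_state`.
#' @param sf_cpd Presented spatial frequency (cpd).
#' @param correct Logical response.
#' @return The updated `staircase_state`.
#' @export
update_posterior <- function(state, sf_cpd, correct) {
  stopifnot(inherits(state, "staircase_state"))
  cfg <- state$config
  if (state$trial_index >= cfg$n_trials)
    stop("staircase already complete (", cfg$n_trials, " trials)", call. = FALSE)
  if (!is.finite(sf_cpd) || sf_cpd <= 0)
    stop("`sf_cpd` must be positive", call. = FALSE)
  lik <- grid_likelihood(sf_cpd, cfg)
  if (!isTRUE(as.logical(correct))) lik <- 1 - lik
  post <- state$posterior * lik
  total <- sum(post)
  if (!is.finite(total) || total <= 0)
    stop("posterior mass vanished during update", call. = FALSE)
  state$posterior <- post / total
  state$trial_index <- state$trial_index + 1L
  state$sf_history[state$trial_index] <- sf_cpd
  state$correct_history[state$trial_index] <- as.logical(correct)
  state
}

posterior_mean_params <- function(state) {
  marg_t <- rowSums(state$posterior)
  marg_s <- colSums(state$posterior)
  c(threshold_log10 = sum(marg_t * state$config$threshold_grid),
    slope = sum(marg_s * state$config$slope_grid))
}

posterior_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Select the next stimulus of an adaptive procedure
#'
#' Under the default posterior-mean rule the next stimulus is the spatial
#' frequency at which the lapse-free logistic with the posterior-mean
#' threshold and slope reaches the target performance; a point-mass
#' posterior therefore reproduces its threshold exactly. Under the
#' entropy-minimisation rule each candidate's expected posterior entropy
#' (over the two possible responses) is evaluated and the minimiser
#' returned. Both rules are deterministic given the state; results are
#' clamped to the candidate range.
#'
#' @param state A `staircase_state`.
#' @return Spatial frequency in cpd.
#' @export
select_stimulus <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  cfg <- state$config
  cand <- cfg$candidate_stimuli_log10
  if (state$trial_index == 0L && !is.null(cfg$start_log10))
    return(10^cfg$start_log10)
  if (cfg$placement_rule == "posterior-mean") {
    pm <- posterior_mean_params(state)
    # solve guess + (1-guess) * plogis(slope*(u - u_alpha)) = target for u
    core <- (cfg$target_performance - cfg$guess_rate) / (1 - cfg$guess_rate)
    u <- -pm["threshold_log10"] + stats::qlogis(core) / pm["slope"]
    sf_log10 <- -u
    sf_log10 <- min(max(sf_log10, min(cand)), max(cand))
    return(unname(10^sf_log10))
  }
  # entropy-min: expected posterior entropy per candidate
  best_sf <- NA_real_; best_h <- Inf
  for (s in cand) {
    lik <- grid_likelihood(10^s, cfg)
    p_correct <- sum(state$posterior * lik)
    post_c <- state$posterior * lik; post_c <- post_c / sum(post_c)
    post_i <- state$posterior * (1 - lik); post_i <- post_i / sum(post_i)
    h <- p_correct * posterior_entropy(post_c) +
      (1 - p_correct) * posterior_entropy(post_i)
    if (h < best_h - 1e-15) { best_h <- h; best_sf <- s }
  }
  10^best_sf
}

#' Final threshold estimate of a completed staircase
#'
#' The posterior mean of the threshold parameter in log10 space,
#' exponentiated to cpd.
#'
#' @param state A `staircase_state` with all trials completed.
#' @return Threshold in cpd.
#' @export
estimate_threshold <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$trial_index < state$config$n_trials)
    stop("staircase incomplete: ", state$trial_index, " of ",
         state$config$n_trials, " trials", call. = FALSE)
  unname(10^posterior_mean_params(state)["threshold_log10"])
}

#' Run one staircase against a response-generating function
#'
#' Drives a full adaptive procedure: each trial's stimulus is chosen by
#' [select_stimulus()], the response is obtained from `respond`, and the
#' posterior updated, until `n_trials` responses have been absorbed.
#'
#' @param config A [staircase_config()].
#' @param respond `function(sf_cpd) -> logical`, the observer.
#' @return The final `staircase_state`.
#' @export
run_staircase <- function(config, respond) {
  state <- staircase_init(config)
  for (i in seq_len(config$n_trials)) {
    sf <- select_stimulus(state)
    state <- update_posterior(state, sf, respond(sf))
  }
  state
}

#' Tidy a staircase state into its trial-by-trial trace
#'
#' @param x A `staircase_state`.
#' @param ... Unused.
#' @return A tibble with one row per completed trial: `trial`, `sf_cpd`,
#'   `correct`. Posterior summaries (`posterior_mean_log10`,
#'   `posterior_sd_log10`) describe the *final* posterior and are repeated
#'   on each row.
#' @export
tidy.staircase_state <- function(x, ...) {
  marg <- rowSums(x$posterior)
  m <- sum(marg * x$config$threshold_grid)
  v <- sum(marg * (x$config$threshold_grid - m)^2)
  k <- seq_len(x$trial_index)
  tibble::tibble(
    trial = k,
    sf_cpd = x$sf_history[k],
    correct = x$correct_history[k],
    posterior_mean_log10 = m,
    posterior_sd_log10 = sqrt(v))
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("Adaptive staircase: %d/%d trials", x$trial_index,
              x$config$n_trials))
  if (x$trial_index > 0) {
    pm <- posterior_mean_params(x)
    cat(sprintf("; posterior-mean threshold %.3f cpd",
                10^pm["threshold_log10"]))
  }
  cat("\n")
  invisible(x)
}
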