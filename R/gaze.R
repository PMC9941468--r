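#' Gaze-trace simulation parameters
#'
#' Controls the synthetic 1 kHz eye traces: fixational jitter (an
#' Ornstein-Uhlenbeck process around the fixation point), and for
#' eye-movement trials a single saccade toward the cued location with
#' direction-dependent latency (downward slowest, reproducing the
#' well-known latency asymmetry), amplitude near the 7.5 degree target
#' eccentricity (rightward largest), Gaussian endpoint scatter, and a
#' smooth raised-cosine speed profile so the velocity-threshold detector
#' has a realistic unimodal signal to find.
#'
#' Latencies are truncated-normal within the admissible response window.
#'
#' @param latency_mean_ms Named numeric, mean saccade latency per cued
#'   direction (ms).
#' @param latency_sd_ms Latency standard deviation (ms).
#' @param latency_range_ms Truncation bounds for latency draws (ms).
#' @param amplitude_mean_deg Named numeric, mean saccade amplitude per
#'   direction (deg).
#' @param landing_sd_deg Isotropic endpoint scatter around the amplitude
#'   point (deg).
#' @param fixation_jitter_sd_deg Stationary SD of fixational jitter (deg).
#' @param jitter_tau_ms Correlation time of the jitter process (ms).
#' @param saccade_duration_ms Saccade duration (ms).
#' @param speed_profile Speed profile identifier; only `"raised-cosine"`
#'   is implemented.
#' @return A `gaze_sim_params` object.
#' @export
gaze_sim_params <- function(latency_mean_ms = c(left = 240, right = 240,
                                                upper = 235, lower = 265),
                            latency_sd_ms = 30,
                            latency_range_ms = c(150, 350),
                            amplitude_mean_deg = c(left = 7.35, right = 7.7,
                                                   upper = 7.45, lower = 7.45),
                            landing_sd_deg = 0.6,
                            fixation_jitter_sd_deg = 0.05,
                            jitter_tau_ms = 20,
                            saccade_duration_ms = 45,
                            speed_profile = "raised-cosine") {
  if (!all(LOCATIONS %in% names(latency_mean_ms)) ||
      !all(LOCATIONS %in% names(amplitude_mean_deg)))
    stop("latency and amplitude means must be named left, right, upper, lower",
         call. = FALSE)
  if (speed_profile != "raised-cosine")
    stop("only the raised-cosine speed profile is implemented", call. = FALSE)
  structure(
    list(latency_mean_ms = latency_mean_ms[LOCATIONS],
         latency_sd_ms = latency_sd_ms,
         latency_range_ms = latency_range_ms,
         amplitude_mean_deg = amplitude_mean_deg[LOCATIONS],
         landing_sd_deg = landing_sd_deg,
         fixation_jitter_sd_deg = fixation_jitter_sd_deg,
         jitter_tau_ms = jitter_tau_ms,
         saccade_duration_ms = saccade_duration_ms,
         speed_profile = speed_profile),
    class = "gaze_sim_params"
  )
}

# Stationary Ornstein-Uhlenbeck (AR(1)) jitter, sd in deg, tau in ms.
ou_jitter <- function(n, sd, tau_ms, dt_ms) {
  phi <- exp(-dt_ms / tau_ms)
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

rtrunc_norm <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  plo <- stats::pnorm(lo, mean, sd); phi_ <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(1, plo, phi_), mean, sd)
}

# Fractional displacement along a raised-cosine speed profile at phase
# u in [0, 1]: integral of (1 - cos(2*pi*u))/2.
raised_cosine_disp <- function(u) {
  u - sin(2 * pi * u) / (2 * pi)
}

#' Simulate the gaze trace of one trial
#'
#' Fixation trials yield pure fixational jitter around the center.
#' Eye-movement trials add exactly one saccade toward the cued location:
#' latency drawn truncated-normal with a direction-dependent mean, straight
#' path with a raised-cosine speed profile, endpoint scattered around the
#' direction's mean amplitude, jitter superimposed throughout. The trace
#' spans cue onset (t = 0) to the response cue. Ground-truth onset,
#' offset, and endpoint are returned alongside for detector validation.
#'
#' @param slot One trial slot (a one-row data frame from [make_design()]),
#'   or a list with `block_type` and `cued_location`.
#' @param gaze A [gaze_sim_params()].
#' @param config A [design_config()]; sampling rates below 250 Hz are
#'   rejected.
#' @return A list with `trace` (tibble `t_ms`, `x_deg`, `y_deg`) and
#'   `annotation` (one-row tibble: `n_saccades`, `true_onset_ms`,
#'   `true_offset_ms`, `true_latency_ms`, `endpoint_x_deg`,
#'   `endpoint_y_deg`).
#' @export
simulate_trace <- function(slot, gaze = gaze_sim_params(),
                           config = design_config()) {
  stopifnot(inherits(gaze, "gaze_sim_params"), inherits(config, "design_config"))
  if (config$sampling_rate_hz < 250)
    stop("sampling rates below 250 Hz are not supported", call. = FALSE)
  dt <- 1000 / config$sampling_rate_hz
  t_end <- config$cue_to_stim_ms + config$stim_duration_ms +
    config$response_cue_delay_ms
  t_ms <- seq(0, t_end, by = dt)
  n <- length(t_ms)
  jx <- ou_jitter(n, gaze$fixation_jitter_sd_deg, gaze$jitter_tau_ms, dt)
  jy <- ou_jitter(n, gaze$fixation_jitter_sd_deg, gaze$jitter_tau_ms, dt)

  if (slot$block_type == "fixation") {
    return(list(
      trace = tibble::tibble(t_ms = t_ms, x_deg = jx, y_deg = jy),
      annotation = tibble::tibble(
        n_saccades = 0L, true_onset_ms = NA_real_, true_offset_ms = NA_real_,
        true_latency_ms = NA_real_, endpoint_x_deg = NA_real_,
        endpoint_y_deg = NA_real_)
    ))
  }

  dir <- slot$cued_location
  latency <- rtrunc_norm(gaze$latency_mean_ms[[dir]], gaze$latency_sd_ms,
                         gaze$latency_range_ms[1], gaze$latency_range_ms[2])
  latency <- round(latency / dt) * dt  # align onset to the sample grid
  unit <- location_xy(dir, 1)
  endpoint <- unit * gaze$amplitude_mean_deg[[dir]] +
    stats::rnorm(2, 0, gaze$landing_sd_deg)
  onset <- latency
  offset <- latency + gaze$saccade_duration_ms
  u <- (t_ms - onset) / gaze$saccade_duration_ms
  frac <- ifelse(u <= 0, 0, ifelse(u >= 1, 1, raised_cosine_disp(pmin(pmax(u, 0), 1))))
  x <- frac * endpoint[1] + jx
  y <- frac * endpoint[2] + jy
  list(
    trace = tibble::tibble(t_ms = t_ms, x_deg = x, y_deg = y),
    annotation = tibble::tibble(
      n_saccades = 1L, true_onset_ms = onset, true_offset_ms = offset,
      true_latency_ms = onset, endpoint_x_deg = endpoint[1],
      endpoint_y_deg = endpoint[2])
  )
}
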