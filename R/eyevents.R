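moving_average <- function(x, n) {
  sm <- stats::filter(x, rep(1 / n, n), sides = 2)
  sm <- as.numeric(sm)
  # pad the filter edges with partial-window means so no sample is lost
  na <- which(is.na(sm))
  if (length(na)) {
    half <- floor(n / 2)
    sm[na] <- vapply(na, function(i) {
      lo <- max(1, i - half); hi <- min(length(x), i + half)
      mean(x[lo:hi])
    }, numeric(1))
  }
  sm
}

#' Velocity-threshold saccade detection
#'
#' Detects saccades in a gaze trace from its speed distribution. Component
#' velocities are computed by central differences and smoothed with a
#' moving average over `smooth_n` consecutive samples; their norm (the
#' smoothed speed) is compared against an adaptive scalar threshold: the
#' median of the smoothed speed plus `k_sd` times a robust scale. The
#' scale is by default the median-based estimate
#' \eqn{\sqrt{\mathrm{med}(v^2) - \mathrm{med}(v)^2}} evaluated on each
#' *signed* velocity component and combined across components (on the
#' nonnegative speed itself this estimator is identically zero, so it must
#' act on the components); the ordinary SD of the smoothed speed is
#' available behind `sd_method = "ordinary"`.
#' A saccade onset is the first sample of a run
#' at least `min_duration_ms` above threshold; its offset is the first
#' sample of the following run at least `min_duration_ms` below threshold.
#' Events separated by less than `min_duration_ms` are merged, which
#' absorbs dynamic overshoots.
#'
#' @param trace Data frame with strictly increasing `t_ms` (uniform
#'   sampling) and `x_deg`, `y_deg`.
#' @param smooth_n Moving-average window in samples.
#' @param k_sd Threshold multiplier.
#' @param min_duration_ms Minimum supra/sub-threshold run length (ms).
#' @param sd_method `"robust"` (default) or `"ordinary"`.
#' @return A tibble of events: `onset_ms`, `offset_ms`, `duration_ms`,
#'   `amplitude_deg`, `peak_speed_deg_s`, `onset_x_deg`, `onset_y_deg`,
#'   `endpoint_x_deg`, `endpoint_y_deg`. Zero rows when no saccade is
#'   found.
#' @examples
#' cfg <- design_config()
#' set.seed(2)
#' tr <- simulate_trace(list(block_type = "saccade", cued_location = "right"),
#'                      gaze_sim_params(), cfg)
#' detect_saccades(tr$trace)
#' @export
detect_saccades <- function(trace, smooth_n = 20, k_sd = 3,
                            min_duration_ms = 20,
                            sd_method = c("robust", "ordinary")) {
  sd_method <- match.arg(sd_method)
  stopifnot(is.data.frame(trace),
            all(c("t_ms", "x_deg", "y_deg") %in% names(trace)))
  n <- nrow(trace)
  if (n < 50) stop("trace too short: need at least 50 samples", call. = FALSE)
  dts <- diff(trace$t_ms)
  if (any(dts <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  if (max(dts) - min(dts) > 1e-6 * stats::median(dts) + 1e-9)
    stop("non-uniform sampling: gaps in the trace", call. = FALSE)
  dt_s <- stats::median(dts) / 1000

  vx <- c(NA, (trace$x_deg[-(1:2)] - trace$x_deg[1:(n - 2)]) / (2 * dt_s), NA)
  vy <- c(NA, (trace$y_deg[-(1:2)] - trace$y_deg[1:(n - 2)]) / (2 * dt_s), NA)
  vx[c(1, n)] <- vx[c(2, n - 1)]
  vy[c(1, n)] <- vy[c(2, n - 1)]
  svx <- moving_average(vx, smooth_n)
  svy <- moving_average(vy, smooth_n)
  vs <- sqrt(svx^2 + svy^2)

  med <- stats::median(vs)
  sdv <- if (sd_method == "robust") {
    # median-based scale per signed velocity component (the robust
    # estimator degenerates to zero on the nonnegative speed itself)
    sx2 <- stats::median(svx^2) - stats::median(svx)^2
    sy2 <- stats::median(svy^2) - stats::median(svy)^2
    sqrt(max(sx2, 0) + max(sy2, 0))
  } else {
    stats::sd(vs)
  }
  threshold <- med + k_sd * sdv

  min_samp <- max(1L, as.integer(round(min_duration_ms / (dt_s * 1000))))
  above <- vs > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  # candidate supra-threshold runs
  cand <- which(r$values)
  if (length(cand) == 0) return(empty_events())
  # merge runs separated by a sub-threshold gap shorter than min_samp
  merged <- list()
  cur <- c(starts[cand[1]], ends[cand[1]])
  for (j in cand[-1]) {
    gap <- starts[j] - cur[2] - 1L
    if (gap < min_samp) {
      cur[2] <- ends[j]
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- c(starts[j], ends[j])
    }
  }
  merged[[length(merged) + 1]] <- cur

  rows <- purrr::map_dfr(merged, function(run) {
    if (run[2] - run[1] + 1L < min_samp) return(NULL)
    onset_i <- run[1]
    offset_i <- min(run[2] + 1L, n)  # first sample of the sub-threshold run
    tibble::tibble(
      onset_ms = trace$t_ms[onset_i],
      offset_ms = trace$t_ms[offset_i],
      duration_ms = trace$t_ms[offset_i] - trace$t_ms[onset_i],
      amplitude_deg = sqrt((trace$x_deg[offset_i] - trace$x_deg[onset_i])^2 +
                             (trace$y_deg[offset_i] - trace$y_deg[onset_i])^2),
      peak_speed_deg_s = max(vs[run[1]:run[2]]),
      onset_x_deg = trace$x_deg[onset_i],
      onset_y_deg = trace$y_deg[onset_i],
      endpoint_x_deg = trace$x_deg[offset_i],
      endpoint_y_deg = trace$y_deg[offset_i])
  })
  if (nrow(rows) == 0) empty_events() else rows
}

empty_events <- function() {
  tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                 duration_ms = numeric(), amplitude_deg = numeric(),
                 peak_speed_deg_s = numeric(), onset_x_deg = numeric(),
                 onset_y_deg = numeric(), endpoint_x_deg = numeric(),
                 endpoint_y_deg = numeric())
}

#' Gate one trial on its detected eye events
#'
#' Applies the offline inclusion criteria in a fixed order so each verdict
#' carries an unambiguous reason. Fixation trials are accepted when gaze
#' never leaves the fixation window and no saccade was detected.
#' Eye-movement trials are accepted when the first post-cue saccade has a
#' latency inside the admissible window, lands within the landing window
#' of the cued location, starts only after stimulus offset, and starts no
#' more than the presaccadic window after stimulus onset (the stimulus
#' must fall entirely within the final interval before the saccade).
#'
#' @param record One-row data frame with `block_type`, `cued_location`,
#'   `cue_onset_ms`, `stim_onset_ms`, `stim_offset_ms`.
#' @param events Event table from [detect_saccades()] for this trial.
#' @param config A [design_config()] supplying windows and limits.
#' @param trace The trial's gaze trace; required to evaluate the fixation
#'   window on fixation trials.
#' @return A one-row tibble: `accepted`, `reason`, `latency_ms`,
#'   `landing_error_deg`, `amplitude_deg` (NA where not applicable).
#' @export
gate_trial <- function(record, events, config = design_config(),
                       trace = NULL) {
  stopifnot(inherits(config, "design_config"))
  need <- c("block_type", "cue_onset_ms", "stim_onset_ms", "stim_offset_ms")
  if (any(!need %in% names(record)) ||
      any(is.na(unlist(record[intersect(need, names(record))][-1]))))
    stop("`record` is missing required timestamps", call. = FALSE)

  verdict <- function(reason, latency = NA_real_, landing = NA_real_,
                      amplitude = NA_real_, ex = NA_real_, ey = NA_real_) {
    tibble::tibble(accepted = reason == "ok", reason = reason,
                   latency_ms = latency, landing_error_deg = landing,
                   amplitude_deg = amplitude,
                   endpoint_x_deg = ex, endpoint_y_deg = ey)
  }

  if (record$block_type == "fixation") {
    if (!is.null(trace)) {
      r <- sqrt(trace$x_deg^2 + trace$y_deg^2)
      if (any(r > config$fixation_window_deg)) return(verdict("fixation_break"))
    }
    if (nrow(events) > 0) return(verdict("fixation_break"))
    return(verdict("ok"))
  }

  post <- events[events$onset_ms > record$cue_onset_ms, , drop = FALSE]
  if (nrow(post) == 0) return(verdict("no_saccade"))
  ev <- post[1, ]
  latency <- ev$onset_ms - record$cue_onset_ms
  target <- location_xy(record$cued_location, config$eccentricity)
  landing <- sqrt((ev$endpoint_x_deg - target[1])^2 +
                    (ev$endpoint_y_deg - target[2])^2)
  vargs <- list(latency, landing, ev$amplitude_deg,
                ev$endpoint_x_deg, ev$endpoint_y_deg)
  if (latency < config$latency_min_ms)
    return(do.call(verdict, c("latency_short", vargs)))
  if (latency > config$latency_max_ms)
    return(do.call(verdict, c("latency_long", vargs)))
  if (landing > config$landing_window_deg)
    return(do.call(verdict, c("landing_out", vargs)))
  if (ev$onset_ms < record$stim_offset_ms)
    return(do.call(verdict, c("early_saccade", vargs)))
  if (ev$onset_ms - record$stim_onset_ms > config$presacc_window_ms)
    return(do.call(verdict, c("stim_not_presaccadic", vargs)))
  do.call(verdict, c("ok", vargs))
}

#' Summarise eye-movement parameters by saccade direction
#'
#' Computes, for accepted eye-movement trials, the per-direction mean
#' saccade latency, amplitude, and landing precision (mean Euclidean
#' distance between endpoint and target center) -- averaged over trials
#' within participant, then over participants -- plus normalized saccade
#' endpoint maps: 2D histograms of endpoints relative to the target center
#' on a fixed grid, scaled to unit maximum per participant and direction
#' before averaging.
#'
#' @param trials Data frame of accepted saccade trials with columns
#'   `participant`, `direction` (cued location), `latency_ms`,
#'   `amplitude_deg`, `landing_error_deg`, `endpoint_x_deg`,
#'   `endpoint_y_deg`.
#' @param config A [design_config()] (for the target eccentricity).
#' @param cell_deg Histogram cell size (deg).
#' @param half_span_deg Histogram half-extent around the target (deg).
#' @return A list with `summary` (tibble: direction, n_trials,
#'   latency_ms, amplitude_deg, landing_error_deg, missing flag) and
#'   `endpoint_maps` (tibble: direction, dx_deg, dy_deg, density).
#' @export
summarize_eye_params <- function(trials, config = design_config(),
                                 cell_deg = 0.25, half_span_deg = 3) {
  stopifnot(is.data.frame(trials))
  dirs <- LOCATIONS
  per_pp <- trials |>
    dplyr::group_by(.data$participant, .data$direction) |>
    dplyr::summarise(latency_ms = mean(.data$latency_ms),
                     amplitude_deg = mean(.data$amplitude_deg),
                     landing_error_deg = mean(.data$landing_error_deg),
                     n_trials = dplyr::n(), .groups = "drop")
  summary <- per_pp |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(n_trials = sum(.data$n_trials),
                     latency_ms = mean(.data$latency_ms),
                     amplitude_deg = mean(.data$amplitude_deg),
                     landing_error_deg = mean(.data$landing_error_deg),
                     .groups = "drop")
  missing <- setdiff(dirs, summary$direction)
  if (length(missing))
    summary <- dplyr::bind_rows(
      summary,
      tibble::tibble(direction = missing, n_trials = 0L, latency_ms = NA_real_,
                     amplitude_deg = NA_real_, landing_error_deg = NA_real_))
  summary <- dplyr::mutate(summary,
                           missing = .data$n_trials == 0,
                           direction = factor(.data$direction, dirs)) |>
    dplyr::arrange(.data$direction)

  edges <- seq(-half_span_deg, half_span_deg, by = cell_deg)
  centers <- edges[-1] - cell_deg / 2
  nm <- length(centers)
  maps <- trials |>
    dplyr::group_split(.data$participant, .data$direction) |>
    purrr::map_dfr(function(g) {
      target <- location_xy(g$direction[1], config$eccentricity)
      dx <- g$endpoint_x_deg - target[1]
      dy <- g$endpoint_y_deg - target[2]
      keep <- abs(dx) <= half_span_deg & abs(dy) <= half_span_deg
      ix <- pmin(pmax(findInterval(dx[keep], edges,
                                   rightmost.closed = TRUE), 1L), nm)
      iy <- pmin(pmax(findInterval(dy[keep], edges,
                                   rightmost.closed = TRUE), 1L), nm)
      h <- matrix(0, nm, nm)
      for (k in seq_along(ix)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1
      if (max(h) > 0) h <- h / max(h)  # unit maximum per participant
      tibble::tibble(participant = g$participant[1], direction = g$direction[1],
                     dx_deg = rep(centers, times = nm),
                     dy_deg = rep(centers, each = nm),
                     density = as.vector(h))
    }) |>
    dplyr::group_by(.data$direction, .data$dx_deg, .data$dy_deg) |>
    dplyr::summarise(density = mean(.data$density), .groups = "drop")

  list(summary = summary, endpoint_maps = maps)
}
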