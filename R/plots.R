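#' Plot a psychometric fit over its binned data
#'
#' @param object A `psy_fit`.
#' @param binned Optional [bin_trials()] tibble to overlay (dot size scales
#'   with trial count).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psy_fit <- function(object, binned = NULL, ...) {
  lo <- object$params$threshold_cpd / 4
  hi <- object$params$threshold_cpd * 4
  if (!is.null(binned)) {
    occ <- binned[binned$n_trials > 0, ]
    lo <- min(lo, min(occ$bin_center_cpd))
    hi <- max(hi, max(occ$bin_center_cpd))
  }
  curve <- tibble::tibble(
    sf_cpd = 10^seq(log10(lo), log10(hi), length.out = 200))
  curve$p <- logistic_prob(curve$sf_cpd, object$params)
  g <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$sf_cpd, y = .data$p)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$params$threshold_cpd,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Spatial frequency (cpd)", y = "Proportion correct") +
    ggplot2::coord_cartesian(ylim = c(0.4, 1))
  if (!is.null(binned)) {
    occ <- binned[binned$n_trials > 0, ]
    occ$prop <- occ$n_correct / occ$n_trials
    g <- g + ggplot2::geom_point(
      data = occ,
      ggplot2::aes(x = .data$bin_center_cpd, y = .data$prop,
                   size = .data$n_trials),
      alpha = 0.6) +
      ggplot2::scale_size_area(max_size = 4, guide = "none")
  }
  g
}

#' Plot a staircase trace
#'
#' Presented spatial frequency per trial, colour-coded by response, with
#' the final posterior-mean threshold.
#'
#' @param object A `staircase_state`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.staircase_state <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$sf_cpd)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$correct)) +
    ggplot2::geom_hline(yintercept = 10^d$posterior_mean_log10[1],
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Trial", y = "Spatial frequency (cpd)",
                  colour = "Correct")
}

#' Plot the normalized performance-field profile
#'
#' Group-mean normalized thresholds per location with per-participant
#' points; the dashed line marks the no-asymmetry profile.
#'
#' @param normalized Output of [normalize_thresholds()].
#' @return A ggplot.
#' @export
plot_threshold_profile <- function(normalized) {
  ord <- c("left", "upper", "right", "lower")
  d <- dplyr::mutate(normalized, location = factor(.data$location, ord))
  g <- d |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(normalized = mean(.data$normalized), .groups = "drop")
  ggplot2::ggplot(g, ggplot2::aes(x = .data$location, y = .data$normalized,
                                  group = 1)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(data = d, alpha = 0.3,
                        position = ggplot2::position_jitter(width = 0.05,
                                                            height = 0)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = NULL, y = "Normalized acuity threshold")
}

#' Plot per-condition thresholds with Cousineau-corrected error bars
#'
#' @param results An `acuity_results` bundle from [run_analyze()].
#' @return A ggplot.
#' @export
plot_condition_effects <- function(results) {
  stopifnot(inherits(results, "acuity_results"))
  d <- dplyr::mutate(results$condition_sem,
                     condition = factor(.data$condition, CONDITIONS))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey30", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "Acuity threshold (cpd)")
}

#' Plot normalized saccade endpoint maps
#'
#' @param eye_params The `eye_params` element of an `acuity_results`
#'   bundle (from [summarize_eye_params()]).
#' @return A ggplot faceted by saccade direction.
#' @export
plot_endpoint_maps <- function(eye_params) {
  ggplot2::ggplot(eye_params$endpoint_maps,
                  ggplot2::aes(x = .data$dx_deg, y = .data$dy_deg,
                               fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~direction) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Horizontal offset from target (deg)",
                  y = "Vertical offset from target (deg)",
                  fill = "Normalized\nfrequency")
}
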