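check_threshold_table <- function(table, conditions = CONDITIONS,
                                  locations = LOCATIONS) {
  need <- c("participant", "condition", "location", "threshold_cpd")
  if (!all(need %in% names(table)))
    stop("threshold table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(table$threshold_cpd)) || any(table$threshold_cpd <= 0))
    stop("all thresholds must be positive and finite", call. = FALSE)
  counts <- table |>
    dplyr::filter(.data$condition %in% conditions) |>
    dplyr::count(.data$participant, .data$condition, .data$location)
  full <- length(conditions) * length(locations)
  bad <- counts |>
    dplyr::count(.data$participant) |>
    dplyr::filter(.data$n != full)
  if (nrow(bad) > 0 || any(counts$n != 1))
    stop("incomplete condition-by-location grid for participant(s): ",
         paste(unique(bad$participant), collapse = ", "), call. = FALSE)
  invisible(table)
}

#' Normalize acuity thresholds by each participant's location average
#'
#' Divides each participant's threshold at every location by that
#' participant's mean threshold over the four locations, isolating the
#' shape of the performance field from overall acuity differences.
#'
#' @param table Threshold table (`participant`, `condition`, `location`,
#'   `threshold_cpd`).
#' @param condition Which condition to profile (default `"baseline"`).
#' @return A tibble with `participant`, `location`, `threshold_cpd`,
#'   `normalized`; per participant the `normalized` values average to 1.
#' @export
normalize_thresholds <- function(table, condition = "baseline") {
  sub <- dplyr::filter(table, .data$condition == !!condition)
  check_threshold_table(sub, conditions = condition)
  sub |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(normalized = .data$threshold_cpd /
                    mean(.data$threshold_cpd)) |>
    dplyr::ungroup() |>
    dplyr::select("participant", "location", "threshold_cpd", "normalized")
}

#' Performance-field asymmetry indices
#'
#' Per participant, the horizontal-vertical anisotropy (HVA) is the mean
#' of the left and right thresholds minus the mean of the upper and lower
#' thresholds; the vertical-meridian asymmetry (VMA) is lower minus upper.
#' Positive values mean better acuity on the horizontal meridian and in
#' the lower visual field, respectively.
#'
#' @param table Threshold table restricted to (or filtered for) one
#'   condition; by default the baseline rows are used.
#' @param condition Condition to evaluate.
#' @return A tibble `participant`, `hva_cpd`, `vma_cpd`.
#' @examples
#' tb <- tibble::tibble(participant = 1, condition = "baseline",
#'                      location = c("left", "right", "upper", "lower"),
#'                      threshold_cpd = c(9.458, 9.609, 6.883, 7.817))
#' asymmetry_indices(tb) # HVA 2.1835, VMA 0.934
#' @export
asymmetry_indices <- function(table, condition = "baseline") {
  sub <- dplyr::filter(table, .data$condition == !!condition)
  check_threshold_table(sub, conditions = condition)
  sub |>
    tidyr::pivot_wider(id_cols = "participant", names_from = "location",
                       values_from = "threshold_cpd") |>
    dplyr::transmute(
      participant = .data$participant,
      hva_cpd = (.data$left + .data$right) / 2 -
        (.data$upper + .data$lower) / 2,
      vma_cpd = .data$lower - .data$upper)
}

#' Presaccadic benefits and costs
#'
#' Per participant: the benefit is the mean over locations of the valid
#' minus baseline thresholds; the cost is the mean of baseline minus
#' invalid. Percentages are relative to the participant's mean baseline
#' threshold.
#'
#' @param table Complete threshold table (all three conditions).
#' @return A tibble `participant`, `benefit_cpd`, `cost_cpd`,
#'   `benefit_pct`, `cost_pct`.
#' @export
presaccadic_effects <- function(table) {
  check_threshold_table(table)
  table |>
    tidyr::pivot_wider(id_cols = c("participant", "location"),
                       names_from = "condition",
                       values_from = "threshold_cpd") |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      benefit_cpd = mean(.data$valid - .data$baseline),
      cost_cpd = mean(.data$baseline - .data$invalid),
      base_mean = mean(.data$baseline), .groups = "drop") |>
    dplyr::mutate(benefit_pct = 100 * .data$benefit_cpd / .data$base_mean,
                  cost_pct = 100 * .data$cost_cpd / .data$base_mean) |>
    dplyr::select(-"base_mean")
}

#' Two-way repeated-measures ANOVA F statistics
#'
#' Hand-rolled within-subject sums-of-squares decomposition for a balanced
#' two-factor repeated-measures design: each effect is tested against its
#' own effect-by-participant interaction. Supports both the 3-by-4
#' condition-by-location analysis and the 2-by-4 difference-score variant.
#'
#' @param data Data frame with columns `participant`, the two factor
#'   columns named in `factors`, and the response in `value`.
#' @param factors Character vector of the two within-subject factor column
#'   names.
#' @param value Name of the response column.
#' @return A tibble: `effect`, `df1`, `df2`, `ss_effect`, `ss_error`,
#'   `F`.
#' @export
rm_anova_F <- function(data, factors = c("condition", "location"),
                       value = "threshold_cpd") {
  stopifnot(length(factors) == 2, all(c("participant", factors, value) %in%
                                        names(data)))
  rm_anova_core(factor(data$participant), factor(data[[factors[1]]]),
                factor(data[[factors[2]]]), data[[value]], factors)
}

rm_anova_core <- function(s, A, B, y, factors) {
  n <- nlevels(s); a <- nlevels(A); b <- nlevels(B)
  if (length(y) != n * a * b || any(table(s, A, B) != 1))
    stop("design must be balanced and complete: one observation per ",
         "participant x ", factors[1], " x ", factors[2], call. = FALSE)

  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean); mS <- tapply(y, s, mean)
  mAB <- tapply(y, list(A, B), mean)
  mAS <- tapply(y, list(A, s), mean)
  mBS <- tapply(y, list(B, s), mean)

  ss_A <- n * b * sum((mA - grand)^2)
  ss_B <- n * a * sum((mB - grand)^2)
  ss_AB <- n * sum((mAB - outer(mA, rep(1, b)) -
                      outer(rep(1, a), mB) + grand)^2)
  ss_AS <- b * sum((mAS - outer(mA, rep(1, n)) -
                      outer(rep(1, a), mS) + grand)^2)
  ss_BS <- a * sum((mBS - outer(mB, rep(1, n)) -
                      outer(rep(1, b), mS) + grand)^2)
  ia <- as.integer(A); ib <- as.integer(B); is_ <- as.integer(s)
  resid <- y - mAB[cbind(ia, ib)] - mAS[cbind(ia, is_)] -
    mBS[cbind(ib, is_)] + mA[ia] + mB[ib] + mS[is_] - grand
  ss_ABS <- sum(resid^2)

  df <- list(A = c(a - 1, (a - 1) * (n - 1)),
             B = c(b - 1, (b - 1) * (n - 1)),
             AB = c((a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1)))
  ss_err <- c(A = ss_AS, B = ss_BS, AB = ss_ABS)
  ss_eff <- c(A = ss_A, B = ss_B, AB = ss_AB)
  eff_names <- c(factors, paste(factors, collapse = ":"))
  Fv <- unname((ss_eff / vapply(df, `[`, numeric(1), 1)) /
                 (ss_err / vapply(df, `[`, numeric(1), 2)))
  Fv[ss_eff == 0] <- 0  # no effect variance: F is 0 even when SS_error = 0
  tibble::tibble(
    effect = eff_names,
    df1 = vapply(df, `[`, numeric(1), 1),
    df2 = vapply(df, `[`, numeric(1), 2),
    ss_effect = unname(ss_eff),
    ss_error = unname(ss_err),
    F = Fv)
}

#' Permutation test with within-participant shuffling
#'
#' Builds the null distribution of an arbitrary statistic by relabelling
#' the data under a scheme that preserves within-subject exchangeability:
#' `"condition-within"` permutes condition labels independently within
#' each participant-by-location stratum (tests condition effects),
#' `"location-within"` the analogue for location, and `"cells-within"`
#' permutes all condition-by-location cells within each participant
#' (omnibus/interaction). The p value is the proportion of null statistics
#' greater than or equal to the observed one, with the observed statistic
#' counted among the `n_iter` replicates -- the smallest attainable p is
#' therefore `1 / n_iter` (0.001 at the default 1000 iterations).
#'
#' @param data Data frame with columns `participant`, `condition`,
#'   `location`, and the response in `value`.
#' @param statistic `function(data) -> scalar`; larger = more extreme.
#' @param scheme Permutation scheme (see above).
#' @param n_iter Number of replicates including the observed one.
#' @param seed Integer seed for the permutation draws.
#' @param value Name of the response column.
#' @return A `perm_test` object: `observed`, `null_stats` (length
#'   `n_iter`), `p`, `n_iter`, `scheme`, `seed`. Has [generics::tidy()].
#' @examples
#' tb <- tidyr::expand_grid(participant = 1:6,
#'                          condition = c("valid", "baseline"),
#'                          location = c("left", "right", "upper", "lower"))
#' tb$threshold_cpd <- 8 + (tb$condition == "valid") * 0.4 + rnorm(nrow(tb), 0, 0.2)
#' stat <- function(d) {
#'   with(d, mean(threshold_cpd[condition == "valid"]) -
#'           mean(threshold_cpd[condition == "baseline"]))
#' }
#' permutation_test(tb, stat, scheme = "condition-within", seed = 1)
#' @export
permutation_test <- function(data, statistic,
                             scheme = c("condition-within", "location-within",
                                        "cells-within"),
                             n_iter = 1000, seed = 1,
                             value = "threshold_cpd") {
  scheme <- match.arg(scheme)
  stopifnot(is.function(statistic),
            all(c("participant", "condition", "location", value) %in%
                  names(data)))
  observed <- statistic(data)
  if (!is.finite(observed) || length(observed) != 1)
    stop("`statistic` must return a finite scalar", call. = FALSE)

  strata <- switch(scheme,
    "condition-within" = interaction(data$participant, data$location,
                                     drop = TRUE),
    "location-within" = interaction(data$participant, data$condition,
                                    drop = TRUE),
    "cells-within" = factor(data$participant))
  idx <- split(seq_len(nrow(data)), strata)
  y <- data[[value]]

  set.seed(seed)
  null_stats <- numeric(n_iter)
  null_stats[1] <- observed
  d <- data
  for (b in 2:n_iter) {
    perm <- unlist(lapply(idx, function(i)
      if (length(i) > 1) i[sample.int(length(i))] else i),
      use.names = FALSE)
    yb <- y
    yb[unlist(idx, use.names = FALSE)] <- y[perm]
    d[[value]] <- yb
    null_stats[b] <- statistic(d)
  }
  p <- mean(null_stats >= observed)
  structure(list(observed = observed, null_stats = null_stats, p = p,
                 n_iter = n_iter, scheme = scheme, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %d iterations): observed %.4f, p = %.3f\n",
              x$scheme, x$n_iter, x$observed, x$p))
  invisible(x)
}

#' Tidy a permutation test
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return One-row tibble: `observed`, `p`, `n_iter`, `scheme`.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(observed = x$observed, p = x$p, n_iter = x$n_iter,
                 scheme = x$scheme)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p values via [stats::p.adjust()] after domain
#' validation.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p values, same length and order.
#' @export
fdr_correct <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Cousineau-corrected within-subject SEM
#'
#' Removes each participant's mean (adding back the grand mean) before
#' computing the per-condition standard error, so error bars reflect
#' within-subject variability only. The Morey sample-size factor
#' (multiplying the variance by m/(m-1) for m conditions) is off by
#' default.
#'
#' @param data Data frame with `participant`, a grouping column, and the
#'   response in `value`.
#' @param group Name of the condition column.
#' @param value Name of the response column.
#' @param morey Apply the Morey correction factor?
#' @return Tibble with one row per level of `group`: `mean`, `sem`,
#'   `n`, plus a `degenerate` flag when only one participant is present.
#' @export
cousineau_sem <- function(data, group = "condition", value = "threshold_cpd",
                          morey = FALSE) {
  stopifnot(all(c("participant", group, value) %in% names(data)))
  grand <- mean(data[[value]])
  centered <- data |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(.y = .data[[value]] - mean(.data[[value]]) + grand) |>
    dplyr::ungroup()
  m <- dplyr::n_distinct(centered[[group]])
  factor_ <- if (morey && m > 1) sqrt(m / (m - 1)) else 1
  centered |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(mean = mean(.data[[value]]),
                     sem = factor_ * stats::sd(.data$.y) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(sem = ifelse(.data$n < 2, 0, .data$sem),
                  degenerate = .data$n < 2)
}

#' Correlate two threshold estimators
#'
#' Pearson correlation, on log10 thresholds, between paired estimates of
#' the same condition-by-location cells (typically the staircase-derived
#' and the refit-derived thresholds), with a pair-shuffling permutation p
#' value.
#'
#' @param x,y Paired numeric vectors of positive thresholds (cpd).
#' @param n_iter Permutation replicates (observed included).
#' @param seed Integer seed.
#' @return One-row tibble: `r`, `p`, `n`, `n_iter`.
#' @export
correlate_estimates <- function(x, y, n_iter = 1000, seed = 1) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("thresholds must be positive", call. = FALSE)
  lx <- log10(x); ly <- log10(y)
  r_obs <- stats::cor(lx, ly)
  set.seed(seed)
  null_r <- numeric(n_iter)
  null_r[1] <- r_obs
  for (b in 2:n_iter) null_r[b] <- stats::cor(lx, sample(ly))
  tibble::tibble(r = r_obs, p = mean(null_r >= r_obs), n = length(x),
                 n_iter = n_iter)
}
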