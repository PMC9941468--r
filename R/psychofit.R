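#' Psychometric parameter set for 2AFC acuity discrimination
#'
#' Bundles the parameters of the two-alternative forced-choice logistic
#' psychometric function used throughout the package. Accuracy is modelled
#' as a function of spatial frequency (cycles per degree, cpd) in *flipped*
#' log space: performance falls as spatial frequency rises, so the model
#' works on \eqn{u = -\log_{10}(SF)}, where the function is increasing.
#'
#' @param threshold_cpd Spatial frequency (cpd) at which accuracy equals the
#'   midpoint of the performance range: 75% correct for guess rate 0.5 and
#'   lapse 0. Must be positive.
#' @param slope Logistic steepness per log10-SF unit. Must be positive.
#' @param guess_rate Lower asymptote; 0.5 for 2AFC.
#' @param lapse_rate Stimulus-independent error probability capping the
#'   upper asymptote at `1 - lapse_rate`.
#'
#' @return An object of class `psy_params` (a named list).
#' @examples
#' p <- psy_params(threshold_cpd = 8, slope = 6)
#' logistic_prob(8, p) # 0.75
#' @export
psy_params <- function(threshold_cpd, slope, guess_rate = 0.5,
                       lapse_rate = 0) {
  stopifnot(is.numeric(threshold_cpd), is.numeric(slope))
  if (threshold_cpd <= 0) stop("`threshold_cpd` must be positive", call. = FALSE)
  if (slope <= 0) stop("`slope` must be positive", call. = FALSE)
  if (guess_rate < 0 || lapse_rate < 0 || guess_rate + lapse_rate >= 1)
    stop("require 0 <= guess_rate, 0 <= lapse_rate, guess_rate + lapse_rate < 1",
         call. = FALSE)
  structure(
    list(threshold_cpd = threshold_cpd, slope = slope,
         guess_rate = guess_rate, lapse_rate = lapse_rate),
    class = "psy_params"
  )
}

#' @export
print.psy_params <- function(x, ...) {
  cat(sprintf(
    "2AFC logistic (flipped log10-SF): threshold %.3f cpd, slope %.2f, guess %.2f, lapse %.3f\n",
    x$threshold_cpd, x$slope, x$guess_rate, x$lapse_rate))
  invisible(x)
}

#' Probability correct under the 2AFC logistic acuity model
#'
#' Evaluates
#' \deqn{p(SF) = \gamma + (1 - \gamma - \lambda)\,
#'   \sigma\!\big(\beta\,(u - u_\alpha)\big)}
#' with \eqn{u = -\log_{10}(SF)}, \eqn{u_\alpha = -\log_{10}(\alpha)}
#' (\eqn{\alpha} the threshold in cpd), guess rate \eqn{\gamma}, lapse rate
#' \eqn{\lambda} and logistic \eqn{\sigma}. The sign flip makes the curve
#' strictly decreasing in spatial frequency: coarse gratings are easy,
#' fine ones fall to chance.
#'
#' @param sf_cpd Spatial frequency in cpd, positive (vectorised).
#' @param params A [psy_params()] object.
#' @return Numeric vector of probabilities in `(guess_rate, 1 - lapse_rate)`.
#' @examples
#' logistic_prob(c(4, 8, 16), psy_params(8, 6))
#' @export
logistic_prob <- function(sf_cpd, params) {
  stopifnot(inherits(params, "psy_params"))
  if (any(!is.finite(sf_cpd)) || any(sf_cpd <= 0))
    stop("`sf_cpd` must be positive and finite", call. = FALSE)
  u <- -log10(sf_cpd)
  u_alpha <- -log10(params$threshold_cpd)
  core <- stats::plogis(params$slope * (u - u_alpha))
  params$guess_rate + (1 - params$guess_rate - params$lapse_rate) * core
}

#' Bin trials into log-spaced spatial-frequency bins
#'
#' Groups the trials of one condition-by-location cell into `n_bins`
#' log-spaced spatial-frequency bins between the minimum and maximum
#' presented frequency, for psychometric refitting and plotting. Bin edges
#' are half-open `[lo, hi)` except the last, which is closed so the maximum
#' stimulus is retained. Empty bins are kept with zero counts.
#'
#' @param trials A data frame with numeric column `sf_cpd` (> 0) and logical
#'   or 0/1 column `correct`.
#' @param n_bins Number of bins (default 20).
#' @return A tibble with columns `bin`, `bin_center_log10`, `bin_center_cpd`,
#'   `n_trials`, `n_correct`.
#' @examples
#' tr <- tibble::tibble(sf_cpd = exp(seq(log(4), log(12), length.out = 160)),
#'                      correct = TRUE)
#' bin_trials(tr)
#' @export
bin_trials <- function(trials, n_bins = 20) {
  stopifnot(is.data.frame(trials))
  if (!all(c("sf_cpd", "correct") %in% names(trials)))
    stop("`trials` needs columns `sf_cpd` and `correct`", call. = FALSE)
  if (nrow(trials) < 1) stop("need at least one trial", call. = FALSE)
  sf <- trials$sf_cpd
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("all `sf_cpd` must be positive and finite", call. = FALSE)
  lo <- min(sf); hi <- max(sf)
  if (lo == hi)
    stop("degenerate spatial-frequency range: all trials at one frequency; ",
         "bin by hand into a single bin", call. = FALSE)
  edges <- 10^seq(log10(lo), log10(hi), length.out = n_bins + 1)
  # half-open [lo, hi); fold the maximum into the last bin
  idx <- findInterval(sf, edges, rightmost.closed = TRUE)
  idx[idx > n_bins] <- n_bins
  centers <- (log10(edges[-1]) + log10(edges[-(n_bins + 1)])) / 2
  correct <- as.logical(trials$correct)
  tibble::tibble(
    bin = seq_len(n_bins),
    bin_center_log10 = centers,
    bin_center_cpd = 10^centers,
    n_trials = tabulate(idx, nbins = n_bins),
    n_correct = as.integer(
      tabulate(idx[correct], nbins = n_bins))
  )
}

# Binomial log-likelihood of binned accuracy under (log10 threshold, slope).
binned_loglik <- function(par, binned, guess_rate, lapse_rate) {
  p <- logistic_prob(binned$bin_center_cpd[binned$n_trials > 0],
                     psy_params(10^par[1], par[2], guess_rate, lapse_rate))
  k <- binned$n_correct[binned$n_trials > 0]
  n <- binned$n_trials[binned$n_trials > 0]
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(k * log(p) + (n - k) * log(1 - p))
}

#' Maximum-likelihood fit of the 2AFC logistic psychometric function
#'
#' Fits threshold and slope to binned accuracy data by maximising the
#' binomial log-likelihood per bin, with multi-start box-constrained
#' optimisation. Guess rate is fixed at 0.5 and the lapse rate at 0 by
#' default, so the returned threshold is exactly the 75% point.
#'
#' The threshold search box is the observed stimulus range widened by 0.5
#' log10 units on each side; slope is bounded in `slope_bounds`. When the
#' data carry no gradient (for example every bin 100% correct) the
#' optimiser pins a bound and the fit is flagged degenerate.
#'
#' @param binned Output of [bin_trials()], or any data frame with columns
#'   `bin_center_cpd`, `n_trials`, `n_correct`.
#' @param guess_rate,lapse_rate Fixed asymptote parameters.
#' @param slope_bounds Length-2 numeric, admissible slope range.
#' @param n_starts Number of optimiser starting points per dimension of the
#'   start grid.
#' @return An object of class `psy_fit`: a list with `params`
#'   ([psy_params()]), `loglik`, `n_trials`, `degenerate` flag and
#'   `convergence` code. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' truth <- psy_params(8, 6)
#' sf <- 10^seq(log10(3), log10(16), length.out = 500)
#' set.seed(1)
#' tr <- tibble::tibble(sf_cpd = sf,
#'                      correct = stats::runif(500) < logistic_prob(sf, truth))
#' fit_psychometric(bin_trials(tr))
#' @export
fit_psychometric <- function(binned, guess_rate = 0.5, lapse_rate = 0,
                             slope_bounds = c(0.25, 40), n_starts = 4) {
  stopifnot(is.data.frame(binned))
  occ <- binned[binned$n_trials > 0, , drop = FALSE]
  if (nrow(occ) < 2)
    stop("need at least 2 occupied bins to fit", call. = FALSE)
  props <- occ$n_correct / occ$n_trials
  rng <- range(log10(occ$bin_center_cpd))
  lower <- c(rng[1] - 0.5, slope_bounds[1])
  upper <- c(rng[2] + 0.5, slope_bounds[2])

  starts <- expand.grid(
    t = seq(lower[1] + 0.05, upper[1] - 0.05, length.out = n_starts),
    s = exp(seq(log(max(slope_bounds[1], 0.5)), log(min(slope_bounds[2], 20)),
                length.out = n_starts)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(c(starts$t[i], starts$s[i]),
                   function(par) -binned_loglik(par, binned, guess_rate, lapse_rate),
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    stop("psychometric fit failed to converge from any start", call. = FALSE)

  eps <- 1e-6
  pinned <- best$par[1] <= lower[1] + eps || best$par[1] >= upper[1] - eps
  degenerate <- pinned || length(unique(round(props, 12))) < 2
  structure(
    list(
      params = psy_params(10^best$par[1], best$par[2], guess_rate, lapse_rate),
      loglik = -best$value,
      n_trials = sum(binned$n_trials),
      degenerate = degenerate,
      convergence = best$convergence
    ),
    class = "psy_fit"
  )
}

#' @export
print.psy_fit <- function(x, ...) {
  cat(sprintf("Psychometric fit: threshold %.3f cpd, slope %.2f, logLik %.2f (n = %d)%s\n",
              x$params$threshold_cpd, x$params$slope, x$loglik, x$n_trials,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a psychometric fit
#'
#' @param x A `psy_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter.
#' @export
tidy.psy_fit <- function(x, ...) {
  tibble::tibble(
    term = c("threshold_cpd", "slope", "guess_rate", "lapse_rate"),
    estimate = c(x$params$threshold_cpd, x$params$slope,
                 x$params$guess_rate, x$params$lapse_rate),
    fixed = c(FALSE, FALSE, TRUE, TRUE)
  )
}

#' One-row summary of a psychometric fit
#'
#' @param x A `psy_fit` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.psy_fit <- function(x, ...) {
  tibble::tibble(
    threshold_cpd = x$params$threshold_cpd,
    slope = x$params$slope,
    loglik = x$loglik,
    n_trials = x$n_trials,
    degenerate = x$degenerate
  )
}

#' Average replicate staircase thresholds with outlier exclusion
#'
#' Combines the threshold estimates of the replicate adaptive procedures run
#' for one condition-by-location cell. An estimate is excluded when its
#' log10 value deviates by strictly more than `criterion_log10` (default
#' 0.1) from the mean log10 of the *other* estimates. Exclusion is applied
#' once, not iterated, and the aggregate is the mean of the surviving
#' estimates in log10 space (a geometric mean in cpd).
#'
#' @param estimates Numeric vector (length >= 2) of positive threshold
#'   estimates in cpd.
#' @param criterion_log10 Outlier criterion in log10 spatial-frequency units.
#' @return A one-row tibble: `value_cpd`, `n_included`, `n_excluded`,
#'   `included` and `excluded` (list columns of indices), `deviation_log10`
#'   (list column, one deviation per input), `all_outlying` flag.
#' @examples
#' aggregate_staircases(c(8, 8, 8, 8 * 10^0.15)) # fourth excluded
#' @export
aggregate_staircases <- function(estimates, criterion_log10 = 0.1) {
  if (length(estimates) < 2 || any(!is.finite(estimates)) || any(estimates <= 0))
    stop("`estimates` must be >= 2 positive finite thresholds (cpd)",
         call. = FALSE)
  le <- log10(estimates)
  n <- length(le)
  # deviation of each estimate from the mean of the others
  dev <- vapply(seq_len(n),
                function(i) abs(le[i] - mean(le[-i])), numeric(1))
  # strict inequality at the criterion; guard the boundary against
  # floating-point noise in the log transform
  out <- dev - criterion_log10 > 1e-12
  all_outlying <- all(out)
  if (all_outlying) {
    warning("all staircase estimates mutually outlying; no exclusion performed",
            call. = FALSE)
    out <- rep(FALSE, n)
  }
  tibble::tibble(
    value_cpd = 10^mean(le[!out]),
    n_included = sum(!out),
    n_excluded = sum(out),
    included = list(which(!out)),
    excluded = list(which(out)),
    deviation_log10 = list(dev),
    all_outlying = all_outlying
  )
}
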