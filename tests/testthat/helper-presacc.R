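# Shared fixtures: compact designs and ideal observers used across tests.

# A consistent scaled-down design: 96 trials, 12 staircases of 8 trials.
small_design <- function(...) {
  design_config(n_fixation_blocks = 1, trials_per_fixation_block = 32,
                n_saccade_blocks = 1, trials_per_saccade_block = 64,
                staircases_per_cell = 1, trials_per_staircase = 8, ...)
}

# Bernoulli responder with the generating psychometric function.
make_responder <- function(params) {
  function(sf) stats::runif(1) < logistic_prob(sf, params)
}

# Synthetic binned data drawn exactly from a psychometric function.
make_binned <- function(params, n_per_bin = 200, n_bins = 20,
                        lo = params$threshold_cpd / 3,
                        hi = params$threshold_cpd * 3) {
  centers <- seq(log10(lo), log10(hi), length.out = n_bins)
  p <- logistic_prob(10^centers, params)
  tibble::tibble(
    bin = seq_len(n_bins),
    bin_center_log10 = centers,
    bin_center_cpd = 10^centers,
    n_trials = rep(n_per_bin, n_bins),
    n_correct = stats::rbinom(n_bins, n_per_bin, p))
}

# Noiseless (expected-count) binned data for deterministic fits.
make_binned_exact <- function(params, n_per_bin = 1e4, n_bins = 20,
                              lo = params$threshold_cpd / 3,
                              hi = params$threshold_cpd * 3) {
  b <- make_binned(params, n_per_bin, n_bins, lo, hi)
  b$n_correct <- round(n_per_bin * logistic_prob(b$bin_center_cpd, params))
  b
}

# Hand-built trace: stationary fixation with optional injected
# raised-cosine saccades. Jitter is smooth by construction.
make_trace <- function(n_ms = 620, saccades = list(), jitter_sd = 0.02,
                       seed = 1) {
  set.seed(seed)
  t_ms <- 0:n_ms
  n <- length(t_ms)
  smooth_noise <- function() {
    z <- stats::rnorm(n, 0, jitter_sd)
    as.numeric(stats::filter(z, rep(1 / 30, 30), sides = 2, circular = TRUE))
  }
  x <- smooth_noise(); y <- smooth_noise()
  for (sc in saccades) {
    u <- (t_ms - sc$onset) / sc$duration
    frac <- pmin(pmax(u, 0), 1)
    frac <- frac - sin(2 * pi * frac) / (2 * pi)
    x <- x + frac * sc$dx
    y <- y + frac * sc$dy
  }
  tibble::tibble(t_ms = t_ms, x_deg = x, y_deg = y)
}
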