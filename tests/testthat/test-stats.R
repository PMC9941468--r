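make_tt <- function(values_by_participant) {
  # values_by_participant: list of named 3x4 matrices (condition x location)
  purrr::imap_dfr(values_by_participant, function(m, p) {
    tidyr::expand_grid(condition = rownames(m), location = colnames(m)) |>
      dplyr::mutate(participant = as.integer(p),
                    threshold_cpd = as.vector(t(m)))
  })
}

full_mat <- function(base = 8, benefit = 0.2, cost = 0.4) {
  m <- matrix(base, 3, 4,
              dimnames = list(c("valid", "baseline", "invalid"),
                              c("left", "right", "upper", "lower")))
  m["valid", ] <- base + benefit
  m["invalid", ] <- base - cost
  m
}

test_that("normalization divides by the participant's location average", {
  tb <- make_tt(list(`1` = full_mat(8, 0, 0)))
  norm <- normalize_thresholds(tb)
  expect_equal(norm$normalized, rep(1, 4))

  m <- full_mat(8, 0, 0)
  m["baseline", ] <- c(10, 10, 6, 8)
  tb <- make_tt(list(`1` = m))
  norm <- normalize_thresholds(tb)
  got <- norm$normalized
  names(got) <- norm$location
  expect_equal(unname(got[c("left", "right", "upper", "lower")]),
               c(10, 10, 6, 8) / 8.5)
  # construction: each participant's normalized profile averages to 1
  expect_equal(mean(norm$normalized), 1)
})

test_that("asymmetry indices reproduce the printed-threshold arithmetic", {
  m <- full_mat()
  m["baseline", ] <- c(9.458, 9.609, 6.883, 7.817)
  a <- asymmetry_indices(make_tt(list(`1` = m)))
  expect_equal(a$hva_cpd, 2.1835, tolerance = 1e-10)
  expect_equal(a$vma_cpd, 0.934, tolerance = 1e-10)

  flat <- full_mat(8, 0, 0)
  a0 <- asymmetry_indices(make_tt(list(`1` = flat)))
  expect_equal(a0$hva_cpd, 0)
  expect_equal(a0$vma_cpd, 0)

  # swapping upper and lower negates VMA, leaves HVA unchanged
  sw <- m[, c("left", "right", "lower", "upper")]
  colnames(sw) <- c("left", "right", "upper", "lower")
  a_sw <- asymmetry_indices(make_tt(list(`1` = sw)))
  expect_equal(a_sw$vma_cpd, -a$vma_cpd)
  expect_equal(a_sw$hva_cpd, a$hva_cpd)
})

test_that("benefits and costs come out in cpd and percent", {
  tb <- make_tt(list(`1` = full_mat(8, 0.2, 0.4)))
  e <- presaccadic_effects(tb)
  expect_equal(e$benefit_cpd, 0.2)
  expect_equal(e$cost_cpd, 0.4)
  expect_equal(e$benefit_pct, 2.5)
  expect_equal(e$cost_pct, 5)

  e0 <- presaccadic_effects(make_tt(list(`1` = full_mat(8, 0, 0))))
  expect_equal(unlist(e0[, -1]), c(benefit_cpd = 0, cost_cpd = 0,
                                   benefit_pct = 0, cost_pct = 0))
  expect_error(presaccadic_effects(
    dplyr::filter(tb, condition != "invalid")), "incomplete")
})

test_that("RM-ANOVA F values match the aov() oracle on random tables", {
  set.seed(33)
  for (n in c(3, 5)) {
    tabs <- lapply(seq_len(n), function(i)
      full_mat(8, 0, 0) + matrix(stats::rnorm(12, 0, 0.5), 3, 4))
    names(tabs) <- seq_len(n)
    tb <- make_tt(tabs)
    got <- rm_anova_F(tb)

    d <- tb
    d$participant <- factor(d$participant)
    d$condition <- factor(d$condition)
    d$location <- factor(d$location)
    fit <- stats::aov(threshold_cpd ~ condition * location +
                        Error(participant / (condition * location)), data = d)
    sm <- summary(fit)
    f_or <- c(
      sm[["Error: participant:condition"]][[1]]["condition", "F value"],
      sm[["Error: participant:location"]][[1]]["location", "F value"],
      sm[["Error: participant:condition:location"]][[1]][
        "condition:location", "F value"])
    expect_equal(got$F, unname(f_or), tolerance = 1e-8)
  }
})

test_that("RM-ANOVA is invariant to participant offsets; flat data give F = 0", {
  set.seed(35)
  tabs <- lapply(1:4, function(i) full_mat(8, 0.2, 0.4) +
                   matrix(stats::rnorm(12, 0, 0.3), 3, 4))
  names(tabs) <- 1:4
  tb <- make_tt(tabs)
  f1 <- rm_anova_F(tb)$F
  shifted <- tb |>
    dplyr::group_by(participant) |>
    dplyr::mutate(threshold_cpd = threshold_cpd + participant * 5) |>
    dplyr::ungroup()
  expect_equal(rm_anova_F(shifted)$F, f1, tolerance = 1e-8)

  flat <- make_tt(list(`1` = full_mat(8, 0, 0), `2` = full_mat(8, 0, 0),
                       `3` = full_mat(8, 0, 0)))
  expect_equal(rm_anova_F(flat)$F, c(0, 0, 0))

  expect_error(rm_anova_F(tb[-1, ]), "balanced")
})

test_that("permutation p floor is 1/n_iter and constants give p = 1", {
  set.seed(37)
  tabs <- lapply(1:12, function(i) full_mat(8, 2, 2) +
                   matrix(stats::rnorm(12, 0, 0.01), 3, 4))
  names(tabs) <- 1:12
  tb <- make_tt(tabs)
  stat <- function(d) {
    mean(d$threshold_cpd[d$condition == "valid"]) -
      mean(d$threshold_cpd[d$condition == "baseline"])
  }
  pt <- permutation_test(dplyr::filter(tb, condition != "invalid"),
                         stat, scheme = "condition-within", seed = 1)
  expect_equal(pt$p, 0.001)
  expect_equal(pt$n_iter, 1000)
  expect_equal(length(pt$null_stats), 1000)
  expect_equal(pt$null_stats[1], pt$observed)

  pc <- permutation_test(tb, function(d) 1, scheme = "cells-within",
                         n_iter = 200, seed = 2)
  expect_equal(pc$p, 1)
  expect_error(permutation_test(tb, stat, scheme = "bogus"), "arg")
})

test_that("permutation tests are reproducible given a seed", {
  set.seed(39)
  tabs <- lapply(1:6, function(i) full_mat() +
                   matrix(stats::rnorm(12, 0, 0.3), 3, 4))
  names(tabs) <- 1:6
  tb <- make_tt(tabs)
  stat <- function(d) rm_anova_F(d)$F[1]
  a <- permutation_test(tb, stat, scheme = "condition-within", n_iter = 100,
                        seed = 7)
  b <- permutation_test(tb, stat, scheme = "condition-within", n_iter = 100,
                        seed = 7)
  expect_identical(a$null_stats, b$null_stats)
})

test_that("BH correction matches hand-computed cases", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_correct(0.2), 0.2)
  expect_equal(fdr_correct(c(0.04, 0.04, 0.04)), c(0.04, 0.04, 0.04))
  # step-up by hand: sorted (0.005, 0.03, 0.04, 0.8) -> raw m*p/i =
  # (0.02, 0.06, 0.0533, 0.8); cumulative min from the top caps 0.06 at
  # 0.0533 before mapping back to the input order
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(fdr_correct(p), c(0.02, 4 * 0.04 / 3, 4 * 0.04 / 3, 0.8),
               tolerance = 1e-12)
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cousineau SEM removes between-participant offsets", {
  base <- tibble::tibble(participant = rep(1:2, each = 2),
                         condition = rep(c("a", "b"), 2),
                         threshold_cpd = c(5, 6, 9, 10))
  out <- cousineau_sem(base)
  expect_equal(out$sem, c(0, 0))

  toy <- tibble::tibble(participant = rep(1:2, each = 2),
                        condition = rep(c("a", "b"), 2),
                        threshold_cpd = c(5, 6, 9, 9))
  got <- cousineau_sem(toy)
  # hand computation: centered values a: (7.25, 6.75), b: (8.25, 8.75)
  expect_equal(got$sem, c(stats::sd(c(7.25, 6.75)) / sqrt(2),
                          stats::sd(c(8.25, 8.75)) / sqrt(2)))
  # Morey factor scales the SEM by sqrt(m/(m-1))
  expect_equal(cousineau_sem(toy, morey = TRUE)$sem, got$sem * sqrt(2))

  single <- tibble::tibble(participant = 1, condition = c("a", "b"),
                           threshold_cpd = c(5, 6))
  s <- cousineau_sem(single)
  expect_true(all(s$degenerate))
  expect_equal(s$sem, c(0, 0))
})

test_that("estimator correlation is 1 for identical and -1 for reversed", {
  x <- 10^seq(0.5, 1.1, length.out = 5)  # log-linear so r is exactly +/-1
  expect_equal(correlate_estimates(x, x, n_iter = 50)$r, 1)
  expect_equal(correlate_estimates(x, rev(x), n_iter = 50)$r, -1)
  expect_error(correlate_estimates(x, x[-1]), "equal length")
})
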