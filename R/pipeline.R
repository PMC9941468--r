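#' Full run configuration
#'
#' Bundles every stage's parameters for a reproducible end-to-end run:
#' the design, the observer and gaze simulators, staircase overrides,
#' detector and statistics settings. Between-participant heterogeneity is
#' introduced by jittering each simulated participant's baseline
#' thresholds in log10 space.
#'
#' @param seed Integer seed (mandatory); all stages derive their streams
#'   from it.
#' @param n_participants Number of simulated observers.
#' @param design A [design_config()].
#' @param obs An [observer_params()] (group-level means).
#' @param gaze A [gaze_sim_params()], or `NULL` for response-only
#'   simulation (no gaze traces, no online rejections).
#' @param between_sd_log10 SD (log10 units) of participant-level baseline
#'   threshold jitter.
#' @param staircase_opts Overrides for [staircase_config()].
#' @param detector Named list of [detect_saccades()] settings.
#' @param n_perm Permutation iterations for the statistics stage.
#' @param store_gaze Keep full traces in memory / on disk.
#' @return A `run_config` object.
#' @export
run_config <- function(seed,
                       n_participants = 12,
                       design = design_config(),
                       obs = observer_params(),
                       gaze = gaze_sim_params(),
                       between_sd_log10 = 0.03,
                       staircase_opts = list(),
                       detector = list(),
                       n_perm = 1000,
                       store_gaze = TRUE) {
  if (missing(seed) || !is.finite(seed))
    stop("`seed` is mandatory", call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  # named atomic vectors must become objects, not bare arrays, so their
  # names survive the JSON round trip
  namedok <- function(x) {
    if (is.list(x)) lapply(x, namedok)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  plain <- namedok(lapply(config, function(x)
    if (is.object(x)) unclass(x) else x))
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  des <- j$design
  run_config(
    seed = j$seed,
    n_participants = j$n_participants,
    design = design_config(
      eccentricity = des$eccentricity,
      n_fixation_blocks = des$n_fixation_blocks,
      trials_per_fixation_block = des$trials_per_fixation_block,
      n_saccade_blocks = des$n_saccade_blocks,
      trials_per_saccade_block = des$trials_per_saccade_block,
      staircases_per_cell = des$staircases_per_cell,
      trials_per_staircase = des$trials_per_staircase,
      cue_to_stim_ms = des$cue_to_stim_ms,
      stim_duration_ms = des$stim_duration_ms,
      response_cue_delay_ms = des$response_cue_delay_ms,
      fixation_window_deg = des$fixation_window_deg,
      landing_window_deg = des$landing_window_deg,
      latency_min_ms = des$latency_min_ms,
      latency_max_ms = des$latency_max_ms,
      presacc_window_ms = des$presacc_window_ms,
      sampling_rate_hz = des$sampling_rate_hz),
    obs = observer_params(
      baseline_threshold_cpd = unlist(j$obs$baseline_threshold_cpd),
      slope = j$obs$slope, lapse_rate = j$obs$lapse_rate,
      guess_rate = j$obs$guess_rate,
      valid_multiplier = j$obs$valid_multiplier,
      invalid_multiplier = j$obs$invalid_multiplier),
    gaze = if (is.null(j$gaze)) NULL else gaze_sim_params(
      latency_mean_ms = unlist(j$gaze$latency_mean_ms),
      latency_sd_ms = j$gaze$latency_sd_ms,
      latency_range_ms = unlist(j$gaze$latency_range_ms),
      amplitude_mean_deg = unlist(j$gaze$amplitude_mean_deg),
      landing_sd_deg = j$gaze$landing_sd_deg,
      fixation_jitter_sd_deg = j$gaze$fixation_jitter_sd_deg,
      jitter_tau_ms = j$gaze$jitter_tau_ms,
      saccade_duration_ms = j$gaze$saccade_duration_ms,
      speed_profile = j$gaze$speed_profile),
    between_sd_log10 = j$between_sd_log10,
    staircase_opts = if (length(j$staircase_opts)) j$staircase_opts else list(),
    detector = if (length(j$detector)) j$detector else list(),
    n_perm = j$n_perm,
    store_gaze = j$store_gaze)
}

participant_observer <- function(config, p) {
  set.seed(config$seed + 7919L * p)
  th <- config$obs$baseline_threshold_cpd *
    10^stats::rnorm(4, 0, config$between_sd_log10)
  observer_params(baseline_threshold_cpd = th,
                  slope = config$obs$slope,
                  lapse_rate = config$obs$lapse_rate,
                  guess_rate = config$obs$guess_rate,
                  valid_multiplier = config$obs$valid_multiplier,
                  invalid_multiplier = config$obs$invalid_multiplier)
}

#' Simulate all participants of a run
#'
#' One [simulate_session()] per participant, with baseline thresholds
#' jittered per participant and per-participant seeds derived from the run
#' seed. Optionally writes the trial tables and gaze stores as TSV.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; trial tables
#'   (`trials_pXX.tsv`), gaze stores (`gaze_pXX.tsv`) and the echoed
#'   configuration (`run_config.json`) are written there.
#' @return Invisibly, the list of `acuity_session` objects.
#' @export
run_simulate <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sessions <- lapply(seq_len(config$n_participants), function(p) {
    obs_p <- participant_observer(config, p)
    simulate_session(config = config$design, obs = obs_p,
                     gaze = config$gaze,
                     seed = config$seed + 1000L * p,
                     participant = p,
                     staircase_opts = config$staircase_opts,
                     store_gaze = config$store_gaze)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
    write_run_config(config, file.path(out_dir, "run_config.json"))
    for (s in sessions) {
      tag <- sprintf("p%02d", s$participant)
      write_tsv_sig(s$trials, file.path(out_dir, paste0("trials_", tag, ".tsv")))
      write_tsv_sig(dplyr::mutate(s$staircase_estimates,
                                  participant = s$participant),
                    file.path(out_dir, paste0("estimates_", tag, ".tsv")))
      dump <- purrr::imap_dfr(s$staircases, function(st, id)
        dplyr::mutate(tidy(st), staircase_id = id, .before = 1))
      write_tsv_sig(dump, file.path(out_dir, paste0("staircases_", tag, ".tsv")))
      if (!is.null(s$gaze))
        write_tsv_sig(s$gaze, file.path(out_dir, paste0("gaze_", tag, ".tsv")))
    }
  }
  invisible(sessions)
}

write_tsv_sig <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Offline gating of one session: detect + gate every trial with a trace.
offline_gate_session <- function(session, detector = list()) {
  if (is.null(session$gaze)) return(NULL)
  config <- session$config
  trials <- session$trials
  by_uid <- split(session$gaze, session$gaze$trial_uid)
  purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    rec <- trials[i, ]
    trace <- by_uid[[rec$trial_uid]]
    if (is.null(trace))
      return(tibble::tibble(trial_uid = rec$trial_uid, accepted = NA,
                            reason = "no_trace", latency_ms = NA_real_,
                            landing_error_deg = NA_real_,
                            amplitude_deg = NA_real_))
    events <- do.call(detect_saccades, c(list(trace = trace), detector))
    v <- gate_trial(rec, events, config, trace = trace)
    dplyr::mutate(v, trial_uid = rec$trial_uid, .before = 1)
  })
}

fit_cell_thresholds <- function(trials) {
  trials |>
    dplyr::group_split(.data$participant, .data$condition, .data$location) |>
    purrr::map_dfr(function(g) {
      fit <- tryCatch(fit_psychometric(bin_trials(g)), error = function(e) NULL)
      tibble::tibble(
        participant = g$participant[1], condition = g$condition[1],
        location = g$location[1],
        threshold_cpd = if (is.null(fit)) NA_real_ else fit$params$threshold_cpd,
        slope = if (is.null(fit)) NA_real_ else fit$params$slope,
        loglik = if (is.null(fit)) NA_real_ else fit$loglik,
        n_trials = nrow(g),
        degenerate = if (is.null(fit)) TRUE else fit$degenerate)
    })
}

#' Analyze simulated (or loaded) sessions end to end
#'
#' Runs the offline stages on a list of sessions: saccade detection and
#' trial gating, staircase-threshold aggregation with outlier exclusion,
#' psychometric refitting on the trials surviving the offline gate, and
#' the group statistics (normalized profiles, asymmetry indices,
#' presaccadic benefits and costs, repeated-measures ANOVA with
#' permutation p values, FDR correction, Cousineau-corrected SEMs, and
#' the between-estimator correlation).
#'
#' @param sessions List of `acuity_session` objects (from
#'   [run_simulate()] or [simulate_session()]).
#' @param config A [run_config()] (for detector and statistics settings).
#' @param out_dir Optional directory for the TSV results bundle and JSON
#'   summary.
#' @return An `acuity_results` list; see Details.
#' @details The returned bundle contains: `thresholds_staircase` and
#'   `thresholds_fit` (per participant-condition-location),
#'   `staircase_outliers`, `normalized_profile` and `group_profile`,
#'   `asymmetries` with `asymmetries_group`, `effects` with
#'   `effects_group`, `anova` (3x4 RM-ANOVA with permutation and
#'   FDR-corrected p values), `effect_tests` (benefit/cost permutation
#'   t tests), `estimator_correlation`, `condition_sem` (Cousineau),
#'   `gating` (per-reason counts), and `eye_params` when gaze traces were
#'   simulated.
#' @export
run_analyze <- function(sessions, config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(sessions, "acuity_session")) sessions <- list(sessions)

  # --- staircase-derived thresholds, with outlier exclusion per cell
  est <- purrr::map_dfr(sessions, function(s)
    dplyr::mutate(s$staircase_estimates, participant = s$participant))
  agg <- est |>
    dplyr::group_split(.data$participant, .data$condition, .data$location) |>
    purrr::map_dfr(function(g) {
      if (nrow(g) == 1) {
        value <- g$threshold_cpd; nex <- 0L
      } else {
        a <- aggregate_staircases(g$threshold_cpd)
        value <- a$value_cpd; nex <- a$n_excluded
      }
      tibble::tibble(participant = g$participant[1],
                     condition = g$condition[1], location = g$location[1],
                     threshold_cpd = value,
                     n_excluded = nex)
    })
  thresholds_staircase <- dplyr::select(agg, -"n_excluded")

  # --- offline gating and psychometric refit
  gates <- purrr::map(sessions, offline_gate_session, detector = config$detector)
  have_gaze <- !vapply(gates, is.null, logical(1))
  all_trials <- purrr::map_dfr(sessions, function(s) s$trials) |>
    dplyr::filter(.data$accepted_online)
  if (any(have_gaze)) {
    gate_tbl <- dplyr::bind_rows(gates[have_gaze])
    fit_input <- all_trials |>
      dplyr::inner_join(dplyr::select(gate_tbl, "trial_uid", "accepted",
                                      offline_reason = "reason"),
                        by = "trial_uid") |>
      dplyr::filter(.data$accepted)
    gating <- gate_tbl |>
      dplyr::count(.data$reason, name = "n_trials")
  } else {
    gate_tbl <- NULL
    fit_input <- all_trials
    gating <- tibble::tibble(reason = "ok", n_trials = nrow(all_trials))
  }
  fit_input <- dplyr::mutate(
    fit_input,
    location = .data$stim_location,
    condition = .data$condition)
  thresholds_fit <- fit_cell_thresholds(fit_input)

  # --- group statistics on the staircase-derived table
  tb <- thresholds_staircase
  normalized <- normalize_thresholds(tb)
  group_profile <- normalized |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(normalized = mean(.data$normalized), .groups = "drop")
  asym <- asymmetry_indices(tb)
  asym_group <- tibble::tibble(
    hva_cpd = mean(asym$hva_cpd),
    hva_sem = stats::sd(asym$hva_cpd) / sqrt(nrow(asym)),
    vma_cpd = mean(asym$vma_cpd),
    vma_sem = stats::sd(asym$vma_cpd) / sqrt(nrow(asym)))
  eff <- presaccadic_effects(tb)
  eff_group <- eff |>
    dplyr::summarise(dplyr::across(c("benefit_cpd", "cost_cpd",
                                     "benefit_pct", "cost_pct"),
                                   list(mean = mean,
                                        sem = ~ stats::sd(.x) / sqrt(length(.x)))))

  n_perm <- config$n_perm
  anova_obs <- rm_anova_F(tb)
  multi <- nrow(dplyr::distinct(tb, .data$participant)) > 1
  if (multi) {
    fs <- factor(tb$participant); fa <- factor(tb$condition)
    fb <- factor(tb$location)
    schemes <- c("condition-within", "location-within", "cells-within")
    perms <- purrr::map2(1:3, schemes, function(i, sch)
      permutation_test(tb, function(d)
        rm_anova_core(fs, fa, fb, d$threshold_cpd,
                      c("condition", "location"))$F[i],
        scheme = sch, n_iter = n_perm, seed = config$seed + i))
    anova <- dplyr::mutate(anova_obs,
                           p_perm = vapply(perms, function(x) x$p, numeric(1)))
    anova$p_fdr <- fdr_correct(anova$p_perm)

    paired_t <- function(d, hi, lo) {
      sgn <- ifelse(d$condition == hi, 1, -1)
      # per-participant mean of (hi - lo) over locations
      diffs <- tapply(sgn * d$threshold_cpd, d$participant, sum) /
        tapply(rep(1, nrow(d)), d$participant, sum) * 2
      mean(diffs) / (stats::sd(diffs) / sqrt(length(diffs)))
    }
    benefit_test <- permutation_test(
      dplyr::filter(tb, .data$condition %in% c("valid", "baseline")),
      function(d) paired_t(d, "valid", "baseline"),
      scheme = "condition-within", n_iter = n_perm, seed = config$seed + 11)
    cost_test <- permutation_test(
      dplyr::filter(tb, .data$condition %in% c("baseline", "invalid")),
      function(d) paired_t(d, "baseline", "invalid"),
      scheme = "condition-within", n_iter = n_perm, seed = config$seed + 12)
    effect_tests <- dplyr::bind_rows(
      dplyr::mutate(tidy(benefit_test), effect = "benefit", .before = 1),
      dplyr::mutate(tidy(cost_test), effect = "cost", .before = 1))
    effect_tests$p_fdr <- fdr_correct(effect_tests$p)
  } else {
    anova <- dplyr::mutate(anova_obs, p_perm = NA_real_, p_fdr = NA_real_)
    effect_tests <- NULL
  }

  pair <- dplyr::inner_join(
    thresholds_staircase,
    dplyr::select(thresholds_fit, "participant", "condition", "location",
                  fit_cpd = "threshold_cpd"),
    by = c("participant", "condition", "location")) |>
    dplyr::filter(is.finite(.data$fit_cpd))
  estimator_correlation <- correlate_estimates(
    pair$threshold_cpd, pair$fit_cpd, n_iter = n_perm,
    seed = config$seed + 13)

  condition_sem <- cousineau_sem(
    tb |> dplyr::group_by(.data$participant, .data$condition) |>
      dplyr::summarise(threshold_cpd = mean(.data$threshold_cpd),
                       .groups = "drop"))

  eye_params <- NULL
  if (any(have_gaze)) {
    acc <- all_trials |>
      dplyr::filter(.data$block_type == "saccade") |>
      dplyr::inner_join(gate_tbl, by = "trial_uid") |>
      dplyr::filter(.data$accepted) |>
      dplyr::mutate(direction = .data$cued_location)
    if (nrow(acc) > 0)
      eye_params <- summarize_eye_params(acc, sessions[[which(have_gaze)[1]]]$config)
  }

  results <- structure(
    list(thresholds_staircase = thresholds_staircase,
         thresholds_fit = thresholds_fit,
         staircase_outliers = dplyr::filter(agg, .data$n_excluded > 0),
         normalized_profile = normalized,
         group_profile = group_profile,
         asymmetries = asym, asymmetries_group = asym_group,
         effects = eff, effects_group = eff_group,
         anova = anova,
         effect_tests = effect_tests,
         estimator_correlation = estimator_correlation,
         condition_sem = condition_sem,
         gating = gating,
         eye_params = eye_params,
         n_perm = n_perm, seed = config$seed),
    class = "acuity_results")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- c("thresholds_staircase", "thresholds_fit", "normalized_profile",
                "group_profile", "asymmetries", "effects", "anova",
                "effect_tests", "condition_sem", "gating")
    for (nm in tables) {
      x <- results[[nm]]
      if (!is.null(x)) write_tsv_sig(x, file.path(out_dir, paste0(nm, ".tsv")))
    }
    summary <- list(
      seed = config$seed, n_perm = n_perm,
      group_profile = results$group_profile,
      asymmetries = results$asymmetries_group,
      effects = results$effects_group,
      estimator_correlation = results$estimator_correlation)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 6, dataframe = "rows")
  }
  results
}

#' @export
print.acuity_results <- function(x, ...) {
  cat("Presaccadic acuity results bundle\n")
  cat(sprintf("  participants: %d, permutation iterations: %d\n",
              dplyr::n_distinct(x$thresholds_staircase$participant), x$n_perm))
  cat(sprintf("  HVA %.3f cpd, VMA %.3f cpd\n",
              x$asymmetries_group$hva_cpd, x$asymmetries_group$vma_cpd))
  cat(sprintf("  benefit %.3f cpd (%.2f%%), cost %.3f cpd (%.2f%%)\n",
              x$effects_group$benefit_cpd_mean, x$effects_group$benefit_pct_mean,
              x$effects_group$cost_cpd_mean, x$effects_group$cost_pct_mean))
  cat(sprintf("  staircase vs fit threshold correlation r = %.3f\n",
              x$estimator_correlation$r))
  invisible(x)
}

#' Validate pipeline input tables
#'
#' Checks trial tables and gaze stores against the package's I/O schema:
#' required columns, positive spatial frequencies, complete
#' condition-by-location coverage per participant, strictly increasing and
#' uniformly sampled timestamps per trial. Returns a report; it never
#' raises for content problems.
#'
#' @param trials Trial table (data frame) or path to its TSV.
#' @param gaze Optional gaze store (data frame) or path to its TSV.
#' @return A tibble of violations (`scope`, `context`, `violation`);
#'   zero rows when everything checks out.
#' @export
validate_inputs <- function(trials, gaze = NULL) {
  read_maybe <- function(x) {
    if (is.character(x)) utils::read.delim(x, sep = "\t",
                                           stringsAsFactors = FALSE)
    else x
  }
  trials <- read_maybe(trials)
  issues <- list()
  note <- function(scope, context, violation)
    issues[[length(issues) + 1]] <<- tibble::tibble(
      scope = scope, context = context, violation = violation)

  need <- c("participant", "block", "block_type", "trial", "condition",
            "cued_location", "stim_location", "staircase_id", "sf_cpd",
            "correct", "cue_onset_ms", "stim_onset_ms", "stim_offset_ms",
            "accepted_online", "reject_reason")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols))
    note("trials", "columns", paste("missing column(s):",
                                    paste(missing_cols, collapse = ", ")))
  if ("sf_cpd" %in% names(trials) &&
      (any(!is.finite(trials$sf_cpd)) || any(trials$sf_cpd <= 0)))
    note("trials", "sf_cpd", "non-positive or missing spatial frequency")
  if (all(c("participant", "condition", "stim_location") %in% names(trials))) {
    cov <- trials |>
      dplyr::distinct(.data$participant, .data$condition, .data$stim_location)
    full <- tidyr::expand_grid(
      participant = unique(trials$participant),
      condition = CONDITIONS, stim_location = LOCATIONS)
    gaps <- dplyr::anti_join(full, cov,
                             by = c("participant", "condition", "stim_location"))
    for (i in seq_len(nrow(gaps)))
      note("trials",
           paste0("participant ", gaps$participant[i]),
           paste0("no trials for ", gaps$condition[i], " x ",
                  gaps$stim_location[i]))
  }

  if (!is.null(gaze)) {
    gaze <- read_maybe(gaze)
    gneed <- c("trial_uid", "t_ms", "x_deg", "y_deg")
    gmiss <- setdiff(gneed, names(gaze))
    if (length(gmiss)) {
      note("gaze", "columns", paste("missing column(s):",
                                    paste(gmiss, collapse = ", ")))
    } else {
      for (uid in unique(gaze$trial_uid)) {
        t <- gaze$t_ms[gaze$trial_uid == uid]
        if (any(diff(t) <= 0)) {
          note("gaze", uid, "timestamps not strictly increasing")
        } else if (length(t) > 2 &&
                   max(diff(t)) - min(diff(t)) >
                   1e-6 * stats::median(diff(t)) + 1e-9) {
          note("gaze", uid, "non-uniform sampling")
        }
      }
    }
  }
  if (length(issues)) dplyr::bind_rows(issues)
  else tibble::tibble(scope = character(), context = character(),
                      violation = character())
}

#' Load simulated sessions back from a simulate output directory
#'
#' Reconstructs the session objects [run_analyze()] needs from the TSV
#' files written by [run_simulate()] (trial tables, staircase estimates,
#' and gaze stores when present) plus the echoed `run_config.json`.
#'
#' @param dir Directory written by [run_simulate()].
#' @return A list of `acuity_session` objects (without posterior states or
#'   ground-truth annotations, which live only in memory).
#' @export
read_session_dir <- function(dir) {
  cfg_path <- file.path(dir, "run_config.json")
  if (!file.exists(cfg_path))
    stop("no run_config.json in ", dir, call. = FALSE)
  config <- read_run_config(cfg_path)
  trial_files <- sort(list.files(dir, "^trials_p[0-9]+\\.tsv$",
                                 full.names = TRUE))
  if (!length(trial_files)) stop("no trial tables in ", dir, call. = FALSE)
  lapply(trial_files, function(f) {
    tag <- sub("^trials_(p[0-9]+)\\.tsv$", "\\1", basename(f))
    trials <- tibble::as_tibble(
      utils::read.delim(f, sep = "\t", stringsAsFactors = FALSE))
    est_f <- file.path(dir, paste0("estimates_", tag, ".tsv"))
    est <- if (file.exists(est_f))
      tibble::as_tibble(utils::read.delim(est_f, sep = "\t",
                                          stringsAsFactors = FALSE))
    else NULL
    gaze_f <- file.path(dir, paste0("gaze_", tag, ".tsv"))
    gaze <- if (file.exists(gaze_f))
      tibble::as_tibble(utils::read.delim(gaze_f, sep = "\t",
                                          stringsAsFactors = FALSE))
    else NULL
    structure(
      list(trials = trials, gaze = gaze, annotations = NULL,
           staircase_estimates = est, staircases = NULL,
           config = config$design, obs = config$obs,
           gaze_params = config$gaze,
           participant = trials$participant[1],
           seed = config$seed),
      class = "acuity_session")
  })
}
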