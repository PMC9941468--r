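# presacc

Simulation and analysis pipelines for **presaccadic visual acuity**: how
the finest resolvable spatial frequency changes around the visual field,
and how it is modulated at the target of an upcoming saccade.

`presacc` is aimed at visual psychophysicists who estimate acuity
(spatial-frequency) thresholds with Bayesian adaptive staircases in
gaze-contingent experiments. It provides, as composable tidyverse-style
functions over plain data frames:

- a **2AFC logistic psychometric model** in flipped log-frequency space,
  `p(f) = γ + (1 − γ − λ) σ(β(u − u_α))` with `u = −log10 f`, so the
  threshold parameter `α` is exactly the 75% point (`logistic_prob()`,
  `bin_trials()`, `fit_psychometric()`);
- a **Bayesian adaptive staircase** engine on a discrete
  threshold × slope grid with posterior-mean (best-PEST-like) or
  expected-entropy (psi-style) stimulus placement
  (`staircase_config()`, `update_posterior()`, `select_stimulus()`,
  `estimate_threshold()`), plus per-meridian start calibration
  (`calibrate_start()`) and geometric-mean aggregation of replicate
  staircases with a strict 0.1 log10 outlier rule
  (`aggregate_staircases()`);
- **velocity-threshold saccade detection** (20-sample moving average,
  median + 3 robust SD, ≥ 20 ms) and **trial gating** on latency,
  landing, and the 150 ms presaccadic stimulus window
  (`detect_saccades()`, `gate_trial()`, `summarize_eye_params()`);
- **permutation statistics** for within-subject designs: repeated-measures
  ANOVA F decomposition, label shuffles that respect participants
  (min p = 0.001 at 1000 iterations), Benjamini–Hochberg FDR, and
  Cousineau-corrected SEMs (`rm_anova_F()`, `permutation_test()`,
  `fdr_correct()`, `cousineau_sem()`, `correlate_estimates()`);
- a **synthetic-observer and gaze simulator** that generates complete
  sessions — 1920 trials, 48 staircases, 1 kHz gaze traces with
  direction-dependent saccade latencies — with known ground truth, so the
  entire pipeline is validated by parameter recovery (`make_design()`,
  `simulate_session()`, `run_simulate()`, `run_analyze()`).

## Worked example

Simulate a 12-participant study at the canonical operating point
(baseline thresholds left/right/upper/lower = 9.458/9.609/6.883/7.817 cpd,
a ~2.5% presaccadic benefit and ~5.9% cost) and analyse it end to end:

```r
library(presacc)

cfg <- run_config(seed = 101, gaze = NULL)   # response-only: fast
sessions <- run_simulate(cfg)
res <- run_analyze(sessions, cfg)
res
#> Presaccadic acuity results bundle
#>   participants: 12, permutation iterations: 1000
#>   HVA 2.175 cpd, VMA 0.648 cpd
#>   benefit 0.218 cpd (2.75%), cost 0.446 cpd (5.23%)
#>   staircase vs fit threshold correlation r = 0.983
```

The bundle reads: baseline acuity is about 2.2 cpd finer on the
horizontal than the vertical meridian (HVA) and about 0.6 cpd finer in
the lower than the upper field (VMA); immediately before a saccade,
thresholds rise by ~0.22 cpd at the saccade target (a benefit) and drop
by ~0.45 cpd at non-target locations (a cost); and the staircases' own
threshold estimates agree with the independent psychometric refit at
r ≈ 0.98. Permutation inference with FDR correction:

```r
res$effect_tests
#> # A tibble: 2 × 7
#>   effect  observed     p n_iter scheme            p_fdr
#>   <chr>      <dbl> <dbl>  <dbl> <chr>             <dbl>
#> 1 benefit     2.10 0.036   1000 condition-within  0.036
#> 2 cost        4.95 0.001   1000 condition-within  0.002

res$anova
#>               effect df1 df2 ss_effect ss_error     F p_perm  p_fdr
#> 1          condition   2  22     11.01     4.75 25.51  0.001 0.0015
#> 2           location   3  33    187.48    36.82 56.01  0.001 0.0015
#> 3 condition:location   6  66      1.37    12.73  1.18  0.330 0.3300
```

With `gaze = gaze_sim_params()` (the default) the simulator also writes
1 kHz gaze traces; `run_analyze()` then detects saccades offline, gates
trials on the latency/landing/presaccadic-window rules, and refits
thresholds from the surviving trials only. Plots:
`autoplot()` on fits and staircases, `plot_threshold_profile()`,
`plot_condition_effects()`, `plot_endpoint_maps()`.

A command-line front end wrapping these functions lives at
`inst/scripts/acuity.R` (`simulate`, `analyze`, `all`, `validate`
subcommands; JSON configs via `write_run_config()`).

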