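---
title: "Methods: adaptive acuity titration, saccade gating, and permutation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive acuity titration, saccade gating, and permutation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presacc)
```

## The scientific problem

Visual acuity — the finest spatial detail an observer can resolve — is not
uniform around the visual field at a fixed eccentricity. At iso-eccentric
locations acuity is better along the horizontal than the vertical meridian
(the horizontal–vertical anisotropy, HVA) and better in the lower than
the upper vertical meridian (the vertical meridian asymmetry, VMA).
Immediately before a saccadic eye movement, attention shifts to the
saccade target and modulates perception there. `presacc` implements the
full measurement-and-analysis machinery needed to quantify these effects:
acuity thresholds are estimated with Bayesian adaptive staircases under
three attentional conditions — `valid` (test at the saccade target),
`invalid` (test at a non-target location), `baseline` (fixation with a
neutral cue) — at four cardinal locations, eye movements are detected
and gated offline, thresholds are refit from the surviving trials, and
group effects are tested with permutation statistics.

Because the package is validated entirely on simulated observers, every
stage can be checked by parameter recovery: we know the ground truth the
synthetic observer obeys and ask whether the pipeline returns it.

## The psychometric model

Orientation discrimination of a stimulus at spatial frequency $f$ (cycles
per degree, cpd) is modelled as a two-alternative forced-choice logistic
in *flipped* log space,

$$
p(f) \;=\; \gamma + (1 - \gamma - \lambda)\,
\sigma\!\left(\beta\,(u - u_\alpha)\right),
\qquad u = -\log_{10} f,
$$

with guess rate $\gamma = 0.5$, lapse rate $\lambda$, slope $\beta$ (per
log10-SF unit), and threshold $\alpha$ in cpd ($u_\alpha = -\log_{10}
\alpha$). The sign flip makes $p$ an increasing function of $u$, i.e.
decreasing in frequency: coarse gratings are easy, fine gratings fall to
chance. With $\gamma = 0.5$ and $\lambda = 0$, $p(\alpha) = 0.75$
exactly, so the threshold parameter *is* the conventional 75% point —
this identity is asserted to $10^{-6}$ in the test suite and is the
package's primary acceptance quantity.

For fitting we keep $\lambda = 0$ fixed. The simulator may use
$\lambda > 0$ (default 0.01); the resulting small upward bias of fitted
thresholds is a property of the estimator we quantify by recovery tests
rather than hide by refitting the lapse. Binned accuracies (20 log-spaced
bins over the presented range, last bin closed so the maximum stimulus is
kept) enter a binomial likelihood maximised by multi-start L-BFGS-B over
$(\log_{10}\alpha, \beta)$, with the threshold constrained to the
stimulus range widened by 0.5 log10 units and $\beta \in [0.25, 40]$.
Fits with no usable gradient (e.g. all bins at ceiling) pin a bound and
are flagged `degenerate`.

## The adaptive staircase

Each condition-by-location cell is titrated by four independent Bayesian
adaptive procedures of 40 trials. The engine maintains a discrete
posterior over a 61-point threshold grid spanning 1.5 log10 cpd upward
from a calibrated lower limit. The slope is held fixed at a single
representative value (15 per log10 unit, QUEST-style) by default; a
log-spaced slope grid is available for marginalisation, but we found in
recovery runs that marginalising over a broad grid roughly doubles the
threshold estimate's standard deviation in 40-trial procedures —
shallow-slope hypotheses are never ruled out by near-threshold data and
keep the posterior diffuse, occasionally letting the placement run away
into the uninformative high-frequency region where 2AFC responses are
coin flips. The session simulator additionally uses a Gaussian prior on
the log10 threshold (SD 0.3) centered on the calibrated starting value;
since the calibration block measured exactly that quantity, this is the
principled Bayesian carry-over of its information, and because all three
conditions at a location share the same prior center, the shrinkage it
induces (under 2% at these information levels) cancels almost entirely
in condition differences.

* **Calibration.** The lower limit per meridian is 0.5 log10 units below
  the mean of that meridian's initial fixation thresholds (left/right for
  horizontal, upper/lower for vertical); the starting stimulus, presented
  on each procedure's first trial, sits at the initial-threshold mean
  itself. All three conditions at a location
  share one calibration, so condition effects cannot be artifacts of
  different starting points.
* **Placement.** The default rule places each trial at the 75% point of
  the lapse-free logistic under the posterior-mean parameters (a
  best-PEST-like rule); an expected-posterior-entropy minimiser
  (psi-style) is selectable, and both must pass the same convergence
  tests. We default to the posterior-mean rule because it is simpler,
  deterministic, and the downstream pipeline is agnostic to the choice.
* **Likelihood.** Inside the engine the response likelihood carries a
  small fixed lapse of 0.005 so a single surprising response cannot
  zero the posterior; placement and the final estimate use the lapse-free
  parameterisation, keeping the estimate exactly the target-performance
  point.
* **Estimate.** The final threshold is the posterior mean of
  $\log_{10}\alpha$, exponentiated. The four replicate estimates are
  averaged in log10 space (a geometric mean — the staircase's native
  scale; at the spreads we observe the difference from an arithmetic mean
  is below half a percent), after excluding estimates that deviate by
  strictly more than 0.1 log10 units from the mean of the other three.
  The exclusion rule is applied once, not iterated.

## The synthetic observer and gaze simulator

The generator defines the conditions under which the pipeline is
validated; its defaults are fixed once:

* **Baseline thresholds** (cpd): left 9.458, right 9.609, upper 6.883,
  lower 7.817 — the canonical operating point with both HVA and VMA.
* **Condition multipliers**: valid 1.025, invalid 0.941, i.e. a ~2.5%
  presaccadic benefit and ~5.9% cost on the threshold scale.
* **Slope** $\beta = 15$ per log10-SF unit. Neither the experimental
  design nor the effect sizes pin this number, so it is our choice of
  realistic steepness: acuity discrimination near the resolution limit
  falls from ceiling to chance within roughly a third of a log10 unit,
  which corresponds to slopes in the mid-teens. The choice matters
  because 40-trial staircase precision is slope-limited (the Fisher
  information of a Bernoulli trial at fixed placement scales with
  $\beta^2$); a much shallower observer would make single-staircase
  estimates too noisy for the small benefit to be detectable at $n=12$ —
  a property of the design, not of the code.
* **Lapse** 0.01; **between-participant jitter** of baseline thresholds
  0.03 log10 units (pipeline level), giving realistic inter-observer
  spread while leaving within-participant effects untouched.
* **Gaze**: fixational jitter is a stationary Ornstein–Uhlenbeck process
  (SD 0.05 deg, 20 ms correlation time) — smooth like drift, unlike
  white noise, whose sample-to-sample velocity at 1 kHz would dwarf any
  physiological signal. Saccades fly a straight path with a raised-cosine
  speed profile (45 ms duration), truncated-normal latencies with
  direction-dependent means (240/240/235/265 ms for left/right/up/down,
  SD 30 ms, truncated to the admissible 150–350 ms window — downward
  slowest, matching the classic latency asymmetry), amplitudes near the
  7.5 deg target eccentricity (rightward largest), and isotropic endpoint
  scatter of 0.6 deg.

What the generator deliberately does **not** emulate: microsaccades,
blinks, post-saccadic oscillations, corrective saccades, pupil-size
artifacts, calibration drift, or any stimulus rendering. Passing tests
therefore show that the algorithms are correct at a realistic operating
point, not that they are robust to every artifact of real recordings.

The session simulator runs the closed loop: each trial's frequency is
requested from its staircase, the gaze trace is simulated, online gating
(fixation window, latency window, landing window, early-saccade rule) is
applied against the generator's own ground-truth annotations — never the
detector, keeping generation and inference separate — and rejected
trials are re-queued at the end of their block, so every staircase always
absorbs its full 40 accepted trials. The staircase state is untouched by
a rejected trial; where a re-queued trial is re-asked, the staircase
simply proposes from its current posterior (the re-ask ordering is
otherwise unconstrained).

## Saccade detection and offline gating

Offline detection works on the speed distribution of each trial's trace:
component velocities by central differences, a 20-sample moving average,
and a scalar threshold at the median speed plus three robust standard
deviations. The robust scale is the median-based estimator
$\sqrt{\mathrm{med}(v^2) - \mathrm{med}(v)^2}$ computed per *signed*
velocity component and combined across components. (On the nonnegative
speed itself this estimator is identically zero — squaring commutes with
the median on nonnegative data — so the component form is the only
faithful reading; the ordinary SD of the speed is available behind
`sd_method = "ordinary"`.) Onsets open a supra-threshold run of at least
20 ms; offsets close it at the first sub-threshold run of 20 ms; events
closer than 20 ms are merged, which absorbs dynamic overshoot.

Trial gating applies, in a fixed order so every verdict has a unique
reason: fixation window → saccade existence → latency in [150, 350] ms →
landing within 2.25 deg of the cued target → stimulus fully presaccadic
(stimulus offset before saccade onset *and* onset-to-onset gap at most
150 ms). The interpretation of "within the last 150 ms before the
saccade" as the conjunction of both containment conditions is a design
choice: either alone would admit stimuli that straddle the movement.

## Group statistics

Thresholds enter a participant × condition × location table. We compute
normalized location profiles (each participant's thresholds divided by
their four-location mean), HVA and VMA indices, and presaccadic benefits
(valid − baseline) and costs (baseline − invalid) in cpd and in percent
of the baseline mean. Inference is permutation-based: a two-way
repeated-measures ANOVA decomposition (each effect tested against its own
effect-by-participant interaction) supplies the F statistics, and null
distributions are built by relabelling within participants — condition
labels within participant × location for condition effects, location
labels within participant × condition for location effects, all twelve
cells within participant for the interaction — preserving within-subject
exchangeability. With 1000 iterations and the observed statistic counted
among the replicates, the smallest attainable p is exactly 0.001.
ANOVAs are run on untransformed cpd (a log-scale analysis is a flag away,
`value` column transformed upstream). Multiple comparisons are corrected
by Benjamini–Hochberg FDR; within-subject error bars use the Cousineau
correction (participant means removed, grand mean restored), without the
Morey factor by default (a flag enables it). Bayes factors are out of
scope; the results schema simply reserves no columns for them.

## Numerical choices and degenerate inputs

* Staircase posteriors are renormalised after every update and checked to
  $10^{-12}$; the final posterior depends only on the multiset of
  (stimulus, response) pairs, not their order.
* The outlier rule's strict inequality is guarded by a $10^{-12}$
  tolerance so that estimates placed exactly at the 0.1 log10 boundary
  are kept.
* Binning with all trials at a single frequency raises a
  degenerate-range error instructing a single-bin fallback rather than
  silently producing empty structure.
* `rm_anova_F` defines $F = 0$ whenever the effect sum of squares is
  zero, covering the all-cells-equal case where both numerator and
  denominator vanish.
* Detector verdicts on traces with gaps or non-monotone timestamps are
  errors, not guesses; the validator reports them per trial.

## Problem sizes used in the tests

The test suite exercises the defaults where the arithmetic demands it
(design layout, 48 × 40 staircase bookkeeping) and scaled-down versions
elsewhere, chosen to keep the suite comfortably reproducible on a laptop:
96-trial sessions (12 staircases of 8 trials) for gaze-loop integration
tests; 200 replicate staircases for threshold-recovery statistics; 500
simulated null datasets for permutation-calibration; 20 replicate
12-participant studies, run in response-only mode (no gaze synthesis, so
no online rejections, with the psychometric refit taken over all
staircase trials), for end-to-end effect recovery. Gaze synthesis and
offline gating are validated end-to-end in their own blocks at smaller n;
at default noise the offline gate removes only a few percent of trials,
so running the recovery study response-only changes the refit estimator
negligibly while making a 20-replicate study practical.

## Known limitations

* The staircase's slope grid tops out at 20; observers materially steeper
  than that are estimated at the grid edge (thresholds remain unbiased in
  our tests, but the slope posterior saturates).
* The refit estimator inherits a small positive bias from the simulator's
  nonzero lapse under the lapse-free fitting model; at the default 0.01
  lapse this is well under the staircase's own sampling noise.
* Endpoint maps use a fixed ±3 deg window around the target; saccades
  landing further away (hypometric by more than the window) fall outside
  the histogram, though they still count toward latency and amplitude
  summaries.
* The permutation schemes assume within-participant exchangeability under
  the null; they are not robust to strong condition-dependent variance
  heterogeneity, which the generator does not produce.
* Detecting the ~2.5% presaccadic benefit with 12 participants operates
  near the information limit of 40-trial adaptive procedures: the Fisher
  information of a Bernoulli trial bounds a 40-trial threshold estimate's
  SD at roughly 0.036 log10 units for a slope-15 observer, which puts the
  expected group-level t for the benefit near 3 even for an ideal
  estimator. Replicate studies at these conditions therefore recover a
  significant benefit in most but not all runs; the (larger) cost is
  recovered essentially always. The recovery tests quantify this rather
  than assume it away.
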