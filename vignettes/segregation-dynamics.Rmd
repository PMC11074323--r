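---
title: "Dynamic network segregation during feedback-driven learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network segregation during feedback-driven learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segdyn)
```

## The scientific question

During feedback-driven stimulus–response learning, whole-brain functional
networks reorganise from a relatively *integrated* configuration (strong
between-network coupling) towards a relatively *segregated* one (strong
within-network coupling, weak or negative between-network coupling). The
package quantifies that transition in a time-resolved way and asks whether
its speed relates to two behavioral quantities estimated from the same
sessions: the **learning rate** (how fast evidence accumulation improves
across stimulus repetitions) and the **habit strength** (the residual pull
of an over-trained response once its reward contingency is removed). The
expected pattern, which the synthetic cohort is built to embody, is a
*negative* correlation between the slope of network segregation across
learning and the learning rate — fast learners segregate early, so they
show less *additional* segregation during the measured session — and a
*null* association with habit strength.

## Pipeline overview

Every stage lives in an exported function; `run_pipeline()` chains them,
and the `analysis/` scripts present the same chain as a stepwise workflow.

1. **Time-series preparation** (`build_fourier_design()`,
   `regress_confounds()`, `qc_motion_exclude()`). Task-evoked activity is
   removed by projecting out a sine basis of 14 harmonics spanning 30 s
   after every trial onset, together with a discrete-cosine high-pass basis
   implementing a 128-s cutoff inside the GLM. Any confound matrix (motion
   parameters, tissue signals, their expansions, break regressors) can be
   appended as extra columns; the operation is agnostic to column meaning.
   Subjects whose frame-wise displacement exceeds 0.2 mm in strictly more
   than 20% of scans are flagged for exclusion.
2. **Windowed connectivity** (`plan_windows()`, `taper_weights()`,
   `weighted_correlation()`, `windowed_fc_stack()`). The scan series is cut
   into 20 windows (non-overlapping by default; a half-overlap mode yields
   the same window count from a series half as long). Within a window of
   length $T$ the scans are weighted by the exponential taper
   $w_t = w_0\,e^{(t-T)/\theta}$, $w_0 = (1-e^{-1/\theta})/(1-e^{-T/\theta})$,
   with $\theta = T/3$, so the weights sum to one exactly and recent scans
   dominate. Node pairs are correlated with the weighted Pearson formula
   (weighted means, weighted central moments) and Fisher z-transformed with
   $|r|$ clipped at $1-10^{-7}$.
3. **Brain states** (`cluster_states()`, `system_segregation()`,
   `label_and_prevalence()`). All subjects' windowed matrices are pooled,
   vectorised as upper triangles, and clustered with k-means under
   city-block distance, $k = 2$, 10 random restarts. Centroids are
   component-wise *medians*: the median is the city-block-consistent
   centroid, so the within-cluster cost is non-increasing across
   iterations (a mean update has no such guarantee under an L1
   assignment rule; this also matches what the standard numerical tools
   do for this distance). States are labelled by centroid *system
   segregation*, $1 - \bar z_b / \bar z_w$, the relative shortfall of mean
   between-network connectivity against mean within-network connectivity;
   per-window prevalence is the fraction of subjects assigned to a state,
   and the two frequencies sum to one by construction.
4. **Modularity and cartography** (`louvain_signed()`,
   `consensus_partition()`, `node_cartography()`, `network_summarize()`).
   Community detection on the full signed weighted matrix avoids
   thresholding. The quality function treats positive and negative weights
   asymmetrically — the positive term carries weight $1/v^+$, the negative
   null term only $1/(v^++v^-)$ — which reduces exactly to Newman–Girvan
   weighted modularity when no negative weights are present. Louvain is
   run at resolution $\gamma = 1$; a consensus partition re-clusters the
   run-agreement matrix (threshold $\tau = 0.5$) until all runs agree.
   Node roles are summarised by the participation coefficient
   $PC_i = 1-\sum_s (k_{is}/k_i)^2$ and the module-degree z-score, both on
   positive weights (a signed variant is deliberately not the default:
   negative strengths make the squared-fraction decomposition
   uninterpretable).
5. **Behavior** (`simulate_ddm_trials()`, `ez_fit()`, `drift_curve()`,
   `fit_learning_rate()`, `habit_strength()`). Two-choice trials are
   accuracy-coded in a drift-diffusion model with boundaries $\{0, a\}$,
   start $a/2$ and unit diffusion. Drift per repetition bin is estimated by
   closed-form moment inversion from accuracy and correct-RT mean and
   variance; the learning rate is $-b$ from the one-term power fit
   $v_k \approx \alpha x_k^b$, $x_k=\log(k+1)$, by least absolute residuals
   (IRLS polish plus direct simplex descent on the L1 objective). Habit
   strength is the compatible-minus-incompatible drift difference, with a
   cohort-level 3-SD discard rule.
6. **Cohort statistics** (`trajectory_features()`, `cohort_statistics()`,
   `cartography_profile()`). Per subject, the Q trajectory is regressed on
   the log cumulative trial count at each window midpoint; the slope is
   the segregation transition rate and the mean of windows 1–3 the early-Q
   value. The battery comprises the one-sample t on Q-slopes, Pearson
   correlations with learning rate and habit strength (early-Q tests
   one-tailed), the paired t on condition drifts, a rank-based median
   split by learning rate, Welch tests between cohorts, and per-network
   one-sample t tests on PC/MDZ slopes with Bonferroni control across
   networks × metrics.

## What the synthetic cohort emulates

`simulate_cohort()` generates the full study: region time series with a
known two-state structure and behavioral trials from a known DDM, with
coupled subject-level parameters. It emulates:

* **Two latent covariance states.** Block correlation matrices over the
  atlas: within/between correlations `tanh(0.3)`/0.20 (integrated) and
  `tanh(0.8)`/−0.05 (segregated), placing the states 0.5 apart in
  within-network Fisher z and giving the segregated state both stronger
  within-network coupling and between-network anticorrelation. Indefinite
  block constructions are repaired by eigenvalue clipping at $10^{-8}$ and
  rescaled to unit diagonal.
* **A rising segregated prevalence.** Scans are partitioned into 2-scan
  segments; each segment's state is Bernoulli with
  $P(\text{segregated}) = \mathrm{logis}(rate\cdot(u - m))$, $u$ the session
  fraction. The midpoint defaults to $m = c_0/rate$ ($c_0 = 1.5$): every
  subject starts near the same low prevalence
  ($\mathrm{logis}(-1.5)\approx 0.18$) and faster subjects complete the
  shift earlier. This choice is load-bearing: with a *fixed* midpoint the
  regression slope of Q on log trials would be flat or *increasing* in the
  transition rate, and the cohort could not reproduce the negative
  slope–learning-rate association it is meant to embody. A fixed
  `midpoint` can still be supplied, which recovers the limit behaviours
  (a step at the midpoint as $rate\to\infty$; a flat 0.5 at $rate = 0$).
  Segments of 2 scans were chosen so that each 35-scan window averages
  many independent state draws, keeping the window-level prevalence close
  to its logistic expectation; they model fast state fluctuation, not the
  multi-window dwell times sometimes reported for resting data.
* **Power-law learning and a null habit coupling.** Phase-2 drift follows
  $v_k = v_{max}\min(1, \alpha\,x_k^b)$ with $v_{max} = 2.5$,
  $\alpha = 0.35$ (accuracy spans roughly 0.7→0.9, and the cap never binds
  for $b \le 0.68$, so the fitter's model family is exactly realisable).
  Transition rate ~ N(16, 4.5²) and exponent ~ N(0.38, 0.16²) — the
  exponent scale of slow-learning cohorts — are drawn jointly at
  correlation `coupling_rho` (default −0.5); the habit effect
  ~ N(0.13, 0.10²) is drawn at `habit_rho` (default 0) to both. The rate
  range sits on the branch where the Q-on-log-trials slope decreases
  monotonically in the rate (verified numerically during design).
  Phase 3 splits the habit effect symmetrically around a baseline drift
  of 1.35 across 96 trials per compatibility condition.

What it does **not** emulate: hemodynamics (no HRF convolution), scanner
noise spectra or motion artefacts (isotropic Gaussian noise only,
sd 0.2), voxel-level structure, dwell-time dynamics of real brain states,
trial-to-trial drift variability, and subject-level variability parameters
of the hierarchical DDM. Passing tests therefore certify the *estimators
and statistics*, not performance on recorded fMRI.

## Numerical choices

* Euler–Maruyama DDM simulation uses dt = 1 ms with the diffusion-bridge
  within-step crossing correction (crossing probability
  $e^{-2(b-x_0)(b-x_1)/s^2 dt}$); without it the discrete walk
  under-absorbs and biases hit probability by about 0.7% at $a = 1.2$.
  Trials not absorbed within 10 s are recorded as omissions and dropped.
* EZ inversion edge-corrects accuracies in $\{0, 0.5, 1\}$ to
  $(x+0.5)/(n+1)$ and inverts from the modal choice's RT moments,
  restoring the drift sign afterwards; all-error subsets yield negative
  drift by the accuracy-coding symmetry.
* The power fit linearises to $\log v = \log\alpha + b\log x$; LAR keeps
  the best of the LS solution, 25 IRLS iterations, and a Nelder-Mead
  descent on the L1 objective (IRLS alone can cycle on a piecewise-linear
  objective).
* Louvain operates on the signed modularity matrix directly, so both
  phases (local moves, aggregation) are exact for the asymmetric quality
  function; sweep order randomisation draws from R's RNG, making every
  run reproducible under `set.seed()`. Ties in best-of-restart selection
  go to the earliest run. Empty k-means clusters are re-seeded at the
  point farthest from its assigned centroid.
* Remainder scans under non-overlapping windowing go one each to the
  earliest windows; window-to-trial alignment uses the cumulative trial
  count at the window midpoint.
* An exact tie in centroid segregation aborts state labelling rather than
  guessing.

## Problem sizes

The default cohort is 40 subjects × 60 nodes (4 networks) × 700 scans,
with 8 stimuli × 98 repetitions in phase 2 (56 trials per 7-repetition
bin, the trial density of a typical overtraining design) and 96 trials
per phase-3 condition. These sizes keep a
full pipeline run around a minute while leaving every formula
size-agnostic; `cohort_config()` scales up to the 227-node, 10-network
regime. The pipeline's consensus default is 20 Louvain runs per window
(the `consensus_partition()` reference default is 500, and its behaviour
is already stable at a few dozen runs on 60-node matrices).

## Known limitations

* **Per-bin drift estimation is information-limited.** At 56 trials per
  bin the closed-form drift estimate has a sampling sd of roughly
  0.25–0.38, and the Cramér–Rao bound for the power-law exponent from 784
  phase-2 trials is about 0.2 — of the same order as the true
  between-subject exponent spread (0.16). Individual learning rates are
  therefore heavily attenuated relative to hierarchical-Bayes estimates
  that pool across subjects, and cohort-level correlations involving the
  learning rate shrink accordingly (roughly by the square root of the
  reliability). The end-to-end tests document this ceiling rather than
  hide it: sign-level recovery of the slope–learning-rate coupling is
  expected, magnitude-level recovery is not.
* The late portion of a log-repetition power curve rises by less per bin
  than the per-bin estimation noise, so rank-based monotonicity of a
  single fitted curve is not a meaningful check; curve-tracking tests
  average replicate sessions.
* Habit strength from 96 trials per condition carries a sampling sd of
  about 0.25 per subject; the paired condition test is correspondingly
  weak at n = 40, exactly as the per-subject inputs dictate.
* The consensus step assumes the agreement matrix has meaningful block
  structure; on structureless matrices it degrades to singleton modules
  (and ultimately to the best single run, with a warning).
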