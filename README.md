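# segdyn — dynamic brain-network segregation during feedback-driven learning

`segdyn` is an R package plus a staged analysis workflow for studying how
whole-brain functional networks shift from an *integrated* towards a
*segregated* configuration while people learn stimulus–response
associations from feedback, and how the speed of that shift relates to
behaviour. It is aimed at network-neuroscience researchers who work with
region-level fMRI time series and two-choice behavioral data.

## What it computes

From region × scan time series (plus a node → network atlas) and
trial-level behavior, the pipeline derives:

* **Tapered windowed connectivity.** The session is cut into 20 sliding
  windows; within a window of length *T* each scan is weighted by
  *w\_t = w₀ e^((t−T)/θ)* with *w₀ = (1−e^(−1/θ))/(1−e^(−T/θ))* and
  *θ = T/3*, and every node pair gets a weighted Pearson correlation,
  Fisher z-transformed.
* **Two brain states.** City-block k-means (k = 2) over all subjects'
  windowed matrices; states are labelled by centroid *system segregation*
  1 − z̄\_b/z̄\_w, and per-window state prevalence traces the
  integrated → segregated transition.
* **Modularity trajectories.** Signed weighted Louvain community detection
  (asymmetric positive/negative null weighting, γ = 1) with 500-run-style
  consensus partitioning per window; the slope of modularity Q on log
  cumulative trials is each subject's segregation transition rate, and
  the mean over windows 1–3 the early-Q value.
* **Node cartography.** Participation coefficient and module-degree
  z-score per node, averaged within a-priori networks, with per-network
  slope tests (Bonferroni FWE).
* **Behavior via the drift-diffusion model.** Closed-form (moment
  inversion) drift estimates per repetition bin; the learning rate is the
  negative exponent of the one-term power fit *v ≈ α·log(k+1)^b* (robust
  LAR); habit strength is the compatible − incompatible drift difference
  with a cohort 3-SD discard rule.
* **The brain–behaviour battery.** One-sample t on Q-slopes, Pearson
  correlations of Q-slope / early-Q with learning rate and habit
  strength, paired condition tests, median-split group Q curves, Welch
  tests between cohorts.

A synthetic-cohort generator (`simulate_cohort()`) produces the full study
with known ground truth — state-switching block-covariance time series
whose segregated prevalence rises along a subject-specific logistic, and
DDM trials whose drift follows a power law — with a configurable coupling
between network transition rate and learning exponent (default −0.5) and
a null habit coupling. Every estimator in the package is validated against
it.

## Worked example: the staged workflow

The `analysis/` scripts run the whole study on the default synthetic
cohort (40 subjects × 60 nodes × 700 scans):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_connectivity.R
Rscript analysis/04_brain_states.R
Rscript analysis/05_modularity.R
Rscript analysis/06_behavior.R
Rscript analysis/07_statistics.R
```

Output from one run (seed 20240501), with tables written under `results/`:

```
simulated 40 subjects: 60 nodes / 4 networks, 700 scans each
realized corr(transition rate, learning exponent) = -0.373
...
centroid system segregation: integrated = 0.841, segregated = 1.065
segregated prevalence: windows 1-3 mean 0.20 -> windows 18-20 mean 0.97
per-window state frequencies sum to 1 exactly
mean Q: window 1 = 0.287 -> window 20 = 0.617
...
learning rate: mean -0.400 (sd 0.313); true exponents mean 0.355
habit strength: mean 0.126 (true effect mean 0.131); 0 outlier(s)
Q-slope one-sample t(39) = 18.48, p = 6.79e-21 (mean slope 0.0855)
r(Q-slope, learning rate) = 0.018 (p = 0.911)
r(Q-slope, habit strength) = 0.050 (p = 0.757)
paired t (compatible vs incompatible drift): t(39) = 2.26, p = 0.030
```

Reading this: the cohort transitions from the integrated state (early
prevalence 0.20) to the segregated one (0.97), mean modularity Q more than
doubles, and the Q-slope is positive in every subject (t(39) = 18.5). The
behavioral stage recovers the generated habit effect (0.126 vs 0.131) and
the learning-rate scale. The Q-slope × learning-rate correlation is the
one quantity that is only weakly recoverable at single-study scale: with
56 trials per drift bin the per-subject learning-rate estimate carries
noise comparable to the true between-subject spread, which attenuates the
cohort correlation towards zero (see the methods vignette,
`vignettes/segregation-dynamics.Rmd`, for the information-limit analysis;
its sign stabilises only across many replications).

The same chain is available as one call:

```r
library(segdyn)
res <- run_pipeline(cohort_config(seed = 1), out_dir = "results/run1")
res$stats$q_slope_t
```

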