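# gipca

Unsupervised classification of gait-initiation kinetics from force-plate
recordings: feature extraction, bootstrap-enhanced principal component
analysis, and Gaussian-mixture clustering.

## What problem it solves

Gait initiation (GI) — the transition from quiet standing to walking — is
preceded by anticipatory postural adjustments (APAs) that are slowed and
hypometric in Parkinson's disease. A force plate yields three forces and
three moments per sample; from one GI trial the package extracts the eleven
standard kinetic variables (per-axis APA durations, per-axis
centre-of-pressure shifts, centre-of-mass velocities at heel-off, toe-off
and heel contact, foot-lift time, and the vertical force peak at heel
contact). Cohorts are then small — typically 10 patients and 10 controls —
which is where the statistical pipeline comes in:

1. **Standardized PCA.** Features are z-scored (they mix s, m, m/s and N)
   and the loadings come from the SVD of the standardized table. Scores
   `t = Z·V_k` live in the subspace of the leading components.
2. **Bootstrap of group means.** Each group's scores are resampled with
   replacement B = 10,000 times; the cloud of replicate means estimates the
   sampling distribution of the group mean, with a 95% confidence ellipse
   roughly `sqrt(n)`-fold tighter per axis than that of the raw scores.
3. **Jaccard overlap.** Separation of the two clouds in a 2-D PC subspace is
   `J = |A ∩ B| / |A ∪ B|`, counting pooled bootstrapped means against the
   two 95% ellipses (membership in a cloud = inside its ellipse).
4. **GMM classification.** A two-component full-covariance Gaussian mixture,
   fit by EM to the pooled clouds without labels, classifies each point;
   the label-aligned confusion matrix reports per-group accuracy.

The package is aimed at movement scientists who want a tested, reproducible
implementation of this chain, plus a seeded synthetic-data generator
(cohorts *and* raw six-channel trials with known ground truth) for
validation and power exploration.

## Worked example

```r
library(gipca)

cohort <- simulate_cohort(cohort_spec(effect = 0.5, seed = 42))
report <- run_pipeline(cohort,
                       config = gi_config(bootstrap.B = 2000, gmm.n_init = 3),
                       seed = 42)
report
#> <gi_report> gait-initiation classification run
#>   20 participants, k = 11 PCs retained (100.00% variance)
#>   PC1/PC2: Jaccard 0.000, GMM accuracy control 100.0%, pd 100.0%
#>   PC2/PC3: Jaccard 0.014, GMM accuracy control 98.0%, pd 98.6%

report$explained[1:3, ]
#> # A tibble: 3 × 3
#>   component fraction cumulative
#>   <chr>        <dbl>      <dbl>
#> 1 PC1         0.300       0.300
#> 2 PC2         0.247       0.546
#> 3 PC3         0.138       0.685

report$subspaces$`PC1/PC2`$confusion
#> <gi_confusion> row percentages (true group x predicted group)
#>          predicted
#> true      control  pd
#>   control     100   0
#>   pd            0 100
#> overall accuracy: 100.0%
```

Reading the output: at `effect = 0.5` (half the default control-vs-PD shift
profile) the bootstrapped-mean clouds of the two groups barely overlap
(Jaccard ≈ 0 in PC1/PC2), and the unsupervised mixture recovers the group
membership of every bootstrapped mean. `k = 11` says that for this small
random cohort the sample correlation spectrum needs all components to reach
the 99.9% cumulative-variance cut; the analyzed subspaces (PC1/PC2,
PC2/PC3) are configurable via `gi_config(subspaces = ...)`.

The kinetics layer works trial-by-trial:

```r
trial <- simulate_trial(trial_spec(noise_sd = 1, seed = 1))
events <- detect_events(trial)            # t0, heel-off, toe-off, heel contact
extract_features(trial, events = events)  # one row, 11 registry variables
```

`autoplot()` methods cover trials, PCA fits and confusion matrices;
`plot_score_clouds()` draws the bootstrapped clouds with their 95%
ellipses. A thin command-line front end is installed under
`inst/scripts/gipca` (`simulate`, `extract`, `fit`, `classify`, `run`).

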