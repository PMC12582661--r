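---
title: "Personalized reference intervals by parametric empirical Bayes: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized reference intervals by parametric empirical Bayes: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# the simulation studies referenced below take minutes; this vignette is a
# methods document and is not evaluated at build time
knitr::opts_chunk$set(eval = FALSE)
library(pebri)
```

## The problem

Conventional laboratory medicine judges a result against a *population*
reference interval: the central 95% of results from a healthy reference
group. For analytes with high *individuality* — where the spread between
people's homeostatic set points dwarfs the fluctuation within one person —
a result can wander far from an individual's own baseline while staying
comfortably inside the population interval, and vice versa. Serial-result
monitoring needs thresholds centred on the *individual's* set point.

The classic tool for serial results is the reference change value (RCV),
which asks whether the difference between two consecutive results exceeds
what within-person and analytical variation alone could produce. The RCV,
however, treats the previous result as a perfect estimate of the set point.
A result that was high partly by chance predicts a next result closer to the
set point — regression toward the mean — so an RCV centred on the raw
previous result is miscentred, and the error is worst for exactly the
analytes where personalized monitoring matters most.

This package implements a parametric empirical Bayes (PEB) framework that
fixes both problems with one estimator, and provides the two estimation
pathways needed to deploy it: mining routine laboratory information system
(LIS) data, and classical biological-variation (BV) studies.

## The model

All inference happens on a *working scale* on which results are normally
distributed — either the natural log or a Box-Cox transform
$t = (x^\lambda - 1)/\lambda$ (with $\lambda = 0$ meaning $\ln x$). On that
scale the model is a two-level Gaussian hierarchy:

* each subject $i$ has a homeostatic set point
  $\mu_i \sim N(\mu_{pop}, \sigma_G^2)$ (between-subject, "G" for genetic /
  group variation);
* each result is $X_{ij} \sim N(\mu_i, \sigma_I^2)$, where $\sigma_I^2$
  combines within-subject biological variation and analytical imprecision.

Writing $\sigma_{pop}^2 = \sigma_G^2 + \sigma_I^2$ for the marginal
(population) variance, the single index that drives everything is the
intraclass correlation

$$B_1 = \frac{\sigma_G^2}{\sigma_G^2 + \sigma_I^2},$$

which is also the regression slope of any result on the previous one from
the same subject. Given $n$ prior results with mean $\bar x_n$, the
empirical-Bayes estimate of the set point shrinks the observed mean toward
the population mean,

$$\hat Y = \mu_{pop} + B_n\,(\bar x_n - \mu_{pop}), \qquad
  B_n = \frac{B_1 n}{B_1 n + (1 - B_1)},$$

and the next result, if the subject is stable, falls in

$$\hat Y \pm Z \sqrt{1 - B_1 B_n}\;\sigma_{pop}$$

with the nominal probability (Z = 1.96 for 95%). This one formula contains
the whole spectrum of thresholds:

* $n = 0$ ($B_n = 0$): the ordinary population reference interval
  $\mu_{pop} \pm Z \sigma_{pop}$;
* $n = 1$ ($B_n = B_1$): an RCV-like result-pair threshold, but centred on
  the *shrunken* baseline and with variance
  $(1 - B_1^2)\sigma_{pop}^2 = (1 + B_1)\sigma_I^2$, strictly narrower than
  the classic RCV's $2\sigma_I^2$ whenever $B_1 < 1$;
* $n \to \infty$: the fully personalized interval $\mu_i \pm Z\sigma_I$.

Because the predictive variance is exact under the hierarchy, the flag rate
for stable subjects is exactly $2\Phi(-Z)$ at every $n$ — the calibration
property the acceptance suite and `scripts/acceptance.R` verify by
simulation (three analyte profiles spanning $B_1 \approx 0.32$–$0.81$ all
flag 5% within Monte-Carlo tolerance).

`peb_parameters()` is the central S3 class: $\mu_{pop}$, $\sigma_{pop}$,
$B_1$, the scale (log or Box-Cox with its $\lambda$). `peb_threshold()`,
`peb_decision()` and the `predict()` method turn a result history into an
interval and a flag; `shrinkage_factor()`, `posterior_mean()` and
`prediction_halfwidth()` expose the pieces.

### Assumptions that matter

The hierarchy assumes (i) a transform to normality exists and is shared by
everyone, (ii) *homoscedasticity*: one $\sigma_I$ for all subjects, and
(iii) stable set points (no drift). Violations of (ii) are the documented
failure mode: subjects whose within-person variation exceeds the population
value are over-flagged, and the package's own simulation reproduces this —
tripling $\sigma_I$ for half the cohort (`heteroscedastic_multiplier = 3`,
`affected_fraction = 0.5`) pushes the dynamic-interval flag rate from 5% to
well above 7.5%. Steroid hormones with strong diurnal or cyclic physiology
are the canonical real-world examples.

## Estimating the parameters

### From routine LIS data — `fit_peb_lis()`

Routine data are a mixture: mostly non-pathological results plus an unknown
pathological fraction, censored below a reporting limit, and collected at
all hours. The pipeline applies, in order, with a per-stage audit trail
(counts in, excluded, retained — `$audit`):

1. **reporting limit / diurnal window** — optional filters; the diurnal
   window (e.g. 08:00–10:00) removes time-of-day physiology the model does
   not represent;
2. **first result per subject** — one result per person estimates the
   population distribution without within-person correlation;
3. **central-peak Box-Cox fit** (`fit_population()`): a grid of $\lambda$
   over $[-1, 2]$ in steps of 0.02; for each $\lambda$ the transformed data
   are reduced to their central region (within $2.5758 \times$ MAD of the
   median) and scored by the Anderson–Darling statistic; the $\lambda$ with
   the smallest statistic wins (ties: the smallest $\lambda$, i.e. the first
   grid point, deterministic). The final $\hat\mu_{pop}$ is the median and
   $\hat\sigma_{pop}$ the MAD on the chosen scale. Median/MAD rather than
   trimmed moments because an iterated-trimming variant proved to bias
   $\hat\sigma$ low by ~11% even on clean data, while median/MAD recovers
   pure Box-Cox-normal parameters within 1% and degrades gracefully under
   20% pathological contamination (the back-transformed centre stays within
   10% where the naive mean does not). The fit refuses fewer than 500 first
   results and warns below 5000;
4. **central-99% filter** (`central99_filter()`): all subsequent steps use
   only results inside $\hat\mu_{pop} \pm 2.5758\,\hat\sigma_{pop}$ — the
   estimated non-pathological core;
5. **sequential pairs** (`build_pairs()`): consecutive results from the same
   subject at least `min_gap_hours = 24` apart (so the pair straddles the
   within-person correlation time, not analytical replication). Unsorted
   timestamps are an error, never silently reordered;
6. **robust regression** (`robust_slope()`): $x_{next}$ on $x_{prev}$ with a
   free intercept, Tukey-bisquare M-estimation (tuning constant 4.685, MAD
   scale, at most 200 IRLS iterations, coefficient tolerance $10^{-8}$).
   The slope is $\hat B_1$. The free intercept is kept (rather than forcing
   the line through $(\mu_{pop}, \mu_{pop})$) so that a residual shift in
   the pair subpopulation cannot leak into the slope. Non-convergence is
   reported in `$converged`, not raised as an error; a degenerate,
   (near-)exactly linear point set — where the MAD scale collapses and IRLS
   is undefined — falls back to the least-squares fit, which is already the
   robust answer there. The 95% CI comes from a nonparametric bootstrap
   (1999 resamples, percentile method, fixed seed) resampling *subjects*,
   not pairs: pairs from one subject share results, and pair-level
   resampling would understate the variance.

Truncating to the central 99% attenuates the slope slightly (observed bias
about $-0.03$ at $B_1 = 0.66$ on a 2500-subject cohort); recovery stays
within $\pm 0.05$ across $B_1 \in \{0.3, 0.5, 0.7, 0.9\}$, which is the
accuracy the framework needs — thresholds are far less sensitive to $B_1$
than to $\sigma_{pop}$.

### From a biological-variation study — `fit_peb_bv()`

A designed BV study (here: 30 subjects × 10 visits, optional duplicate
analyses) yields the classical coefficients of variation $CV_G$, $CV_I$,
$CV_A$ (percent, original scale). The pathway:

1. **outlier cascade** (`outlier_cascade()`), applied in the conventional
   order, each level on the data surviving the previous one:
   analytical — a Burnett-type per-sample chi-square test of replicate
   scatter against the pooled analytical variance (Bonferroni-adjusted,
   `alpha_burnett = 0.05`); subject means — the Reed criterion, iterated at
   both extremes (exclude when the gap to the nearest mean exceeds one third
   of the range); trend — per-subject linear regression on visit index,
   excluding subjects with slope $p <$ `trend_p = 0.01`; variance
   homogeneity — Bartlett's test (or Cochran's C) on within-subject
   variances, iteratively excluding the subject with the most extreme
   variance until the test passes. Ties at any level are broken toward the
   most extreme statistic; every exclusion is recorded with its level and
   test value. Reducing the data below three subjects is an error
   ("cascade failure"), not a silent degenerate fit;
2. **nested ANOVA** (`nested_anova_cv()`), method-of-moments on the balanced
   two-level design, in one of two modes: `ln_anova` (components on the log
   scale, converted by $CV = 100\sqrt{e^{v}-1}$ — exact under the lognormal
   model, the default) or `cv_anova` (components directly as squared CVs on
   the original scale — the traditional approximation, good for CVs below
   ~15–20%; a test pins their agreement in that regime). $CV_I$ is reported
   net of the analytical component, negative moment estimates are truncated
   at zero with a warning, and designs missing more than 20% of any
   subject's visits are refused as unbalanced;
3. **conversion** (`bv_estimates()` + `bv_to_peb()`): with CVs in percent,
   $\sigma_I^2 = \ln(1 + (CV_I^2 + CV_A^2)/10^4)$,
   $\sigma_G^2 = \ln(1 + CV_G^2/10^4)$, $\mu_{pop} = \ln(\text{mean})$,
   giving log-scale PEB parameters. Analytical imprecision deliberately
   stays inside $\sigma_I$: the monitored quantity is the *measured* result.

## The synthetic cohort generator

`simulation_config()` + `simulate_cohort()` generate cohorts from exactly
the hierarchy above, on the log scale (or a Box-Cox shape via the delta
method), plus the artifacts the estimators must survive — each off by
default and switched on explicitly:

* `pathological_fraction` / `pathological_shift_sd`: a fraction of subjects
  whose set points are shifted by a multiple of $\sigma_{pop}$ — the
  contamination the central-peak fit is built for;
* `reporting_limit`: left-censoring, with censored rows labelled rather than
  dropped;
* `morning_window` / `gap_hours_range`: realistic timestamps (08:00–10:00
  draws, 6–8 days between visits) so the diurnal and pair-gap filters have
  something to act on;
* `heteroscedastic_multiplier` / `affected_fraction`: the homoscedasticity
  violation discussed above;
* `simulate_bv_study()` adds balanced replicate designs with optional
  engineered faults (a drifting subject, a variance-inflated subject) for
  the cascade tests.

One detail worth recording: the generator adds within-person and analytical
noise as *separate* log-scale components with $\sigma^2 = \ln(1 + CV^2)$
each, while `bv_estimates()` converts the combined CV. The two conventions
differ by $O(CV^4)$ — about 0.3% of the working variance at $CV = 50%$ —
far below every tolerance used; it is a modelling convention, not an error.

What the generator does *not* emulate — and therefore what passing tests do
not certify about real data: set-point drift with age or season, analytical
bias shifts between instrument recalibrations, non-lognormal heavy tails,
correlated missingness, and pathological *episodes* (transient excursions)
as opposed to shifted set points. Results on real LIS extracts additionally
depend on data-quality filtering not modelled here.

## Reproducibility and numerical conventions

* All simulation entry points take explicit seeds and restore the caller's
  RNG state; one seeded stream per cohort (simpler than per-subject
  sub-streams, and fully reproducible).
* Flagging uses strict inequalities: a result exactly on a limit is not
  flagged.
* Box-Cox transforms treat $|\lambda| < 10^{-8}$ as the log branch; inverse
  transforms refuse values outside the image of the forward transform
  rather than returning NaN; thresholds whose lower working limit falls
  outside the image clamp to 0 on the original scale.
* `b1` values slightly outside $[0, 1]$ from sampling noise are clipped with
  a warning inside $[-0.1, 1.1]$; beyond that, an error.
* Parameter files round-trip value-identically (written with 17 significant
  digits).

## Known limitations

The framework is univariate and assumes steady state; it does not model
treatment effects, drift, or between-laboratory transfer of parameters. The
LIS pathway estimates *measured-result* variation: $B_1$ from an instrument
with poor imprecision is genuinely lower, and personalized intervals
correspondingly wider. Parameters estimated on one population (age range,
sex mix, clinic type) should not be assumed to transfer.
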