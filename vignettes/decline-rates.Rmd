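---
title: "Estimating yearly decline rates from age-aggregated spine-imaging summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating yearly decline rates from age-aggregated spine-imaging summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedecline)
```

## The problem

Imaging studies of asymptomatic adults report degeneration of the lumbar
spine almost exclusively in age-aggregated form: the fraction of subjects
per age decade showing a feature (disk degeneration, disk signal loss,
facet degeneration, ...), or per-age-group means and standard deviations of
a continuous marker such as the fat-infiltration percentage (FI%) of the
paravertebral muscles (multifidus, erector spinae, psoas). Individual-level
data are rarely available, yet the scientifically interesting quantity is a
*rate*: how many percentage points per year of adult life does each feature
decline, and how do the spinal column and the musculature compare?

`spinedecline` answers this by reconstructing synthetic individual-level
samples that are exactly (binary outcomes) or distributionally (continuous
outcomes) consistent with the aggregates, fitting age-trend regressions to
the reconstructed samples, and reporting each endpoint's yearly decline
with a 95% confidence interval on a common %/year scale.

The bundled reference tables (`spine_fixtures()`) cover 15 endpoints in
asymptomatic adults aged roughly 18–60: eight spinal-column prevalence
endpoints pooled by decade from a large imaging meta-analysis, and seven
muscle FI% endpoints from two quantitative MRI cohorts — one reporting four
decade groups of n = 20, one reporting two age groups (18–25, 45–60) of
n = 12.

## The two reconstruction models

### Binary endpoints: deterministic expansion and logistic AME

A prevalence table gives, per age group *j*, a sample size $n_j$ and a
prevalence $\pi_j$ (in %). `expand_prevalence()` creates $n_j$ records at
the group's representative age, of which

$$k_j = \mathrm{round}\!\left(n_j \pi_j / 100\right)$$

(rounding half away from zero) carry outcome 1. This construction is
deterministic on purpose: the published proportions are fixed quantities,
so re-randomising them per subject would only inject noise the source data
do not contain. The rounding rule is the one that reproduces the published
per-group case counts (e.g. 37% of 273 → 101 positives).

The reconstructed records are fitted by maximum-likelihood logistic
regression of outcome on age,
$\operatorname{logit} P(Y=1) = \beta_0 + \beta_1 \cdot \mathrm{age}$,
and the reported decline rate is the **average marginal effect** (AME) of a
one-year age increase, in percentage points per year:

$$\mathrm{AME} = \frac{100}{n}\sum_i \hat\beta_1\,\hat p_i(1-\hat p_i),
\qquad \hat p_i = \operatorname{logit}^{-1}(\hat\beta_0+\hat\beta_1 x_i).$$

Averaging over the sample (rather than evaluating at the mean age) is the
convention of the major econometric/epidemiological software; it is also
the only flavour consistent with the reference results the acceptance
checks reproduce. The AME's standard error comes from the delta method over
the full $2\times 2$ coefficient covariance, and the interval is
$\mathrm{AME} \pm 1.96\,\mathrm{se}$. The delta-method gradient is checked
in the test suite against a finite-difference Jacobian (agreement 1e-6) and
a 100,000-draw parametric bootstrap. The bootstrap check is a reminder that
the delta method is first-order: for the smallest endpoint
(spondylolisthesis, n = 284, prevalences 3–14%) the bootstrap SE sits about
6% above the delta SE because the AME is visibly curved in the
coefficients there; for the larger endpoints the two agree within 2%.

### Continuous endpoints: Monte Carlo over normal reconstructions

A continuous table gives, per group *j*, $(s_j, \mu_j, \sigma_j)$: sample
size, mean FI% and SD. There is no deterministic reconstruction consistent
with only those moments, so `run_mc()` simulates: each iteration draws
$s_j$ variates from $\mathcal N(\mu_j, \sigma_j)$ per group
(`draw_continuous()`), regresses the pooled sample on age by ordinary least
squares, and records the slope $b$ and its standard error
$\mathrm{se}(b)$. After $M$ iterations (default $M = 10{,}000$) the engine
reports mean/SD/min/max of both. The decline estimate is
$\overline b$, and the default interval is

$$\overline b \pm 1.96\,\overline{\mathrm{se}(b)} ,$$

i.e. the average *within-iteration* uncertainty, not the spread of $b$
across iterations. The two coincide in expectation here (each iteration is
an independent honest sample of the same size as the source study), and
this construction is the one that matches the reference intervals; the
empirical 2.5/97.5 percentile interval of $b$ is available via
`ci_method = "percentile"`.

Draws are deliberately **not truncated** to [0, 100] FI%: truncation would
bias the group means away from the published $\mu_j$ that the simulation
is defined to preserve. With the bundled tables the probability mass below
0 is negligible anyway (the smallest $\mu_j/\sigma_j$ ratio is about 2.7).

Because the per-iteration OLS slope is linear in the draws, its exact
expectation is the group-size-weighted OLS slope through the group means —
exposed as `expected_slope()` and used throughout the tests as an analytic
convergence oracle. At $M = 10{,}000$ the Monte Carlo error of
$\overline b$ is $\mathrm{SD}(b)/100$, i.e. third-decimal accuracy for
every bundled endpoint.

## Representative ages

Grouped data need one age per group. Two schemes are defaults:

* decade-binned tables (`"decade"`): equally spaced 25, 35, 45, 55. Any
  equally spaced coding of equal-width groups gives identical slopes; the
  25-series is used for readability. This is also applied to the
  four-decade muscle cohort whose last bin is 50–60: the published
  regression results are consistent with equal spacing, not with the exact
  midpoint 55.5 of the last bin.
* the two-group muscle cohort (`"midpoint"`): true midpoints 21.5 and
  52.5, validated against the published slopes (for a two-group design the
  slope is just $\Delta\mu / \Delta\mathrm{age}$, so the age gap matters).

An explicit per-group list is always available
(`representative_ages(..., "explicit")`). Slopes, their SEs and AMEs are
invariant under adding a constant to all representative ages (tested to
1e-10); only the spacing matters.

## Linearity of the age trend

Using a single linear age predictor is an assumption. It is checked per
endpoint by a likelihood-ratio test of the linear model against the
saturated model (one parameter per age group):
$\mathrm{LR} = 2(\ell_{\mathrm{sat}} - \ell_{\mathrm{lin}})$ on
$k - 2$ df. For two-group designs the linear model is saturated; the
statistic is 0 on 0 df and the p-value is reported as 1. For continuous
endpoints the check necessarily runs on one seeded reconstruction, so it is
a property of that draw, not of the aggregate itself; across seeds the
erector-spinae decade endpoint, whose group means are the least linear,
can come close to the 0.05 line. All 15 bundled endpoints pass the check
at the seeds fixed in the test suite.

## The parameter-recovery generator

`recovery_aggregate(true_slope, true_intercept, noise_sd, groups)`
fabricates a continuous table whose group means lie exactly on a known
line. It emulates the *aggregate* structure of the real tables (groups,
sizes, means, SDs) with a known ground truth, which no published table
has; the test suite demands that the full Monte Carlo pipeline recovers
slopes of −0.3, 0 and +0.3 %/year within Monte Carlo tolerance
($4\,\mathrm{SD}(b)/\sqrt{M}$).

What the generator does **not** emulate — and therefore what passing
recovery tests cannot certify about real data: within-group age variation
(all subjects in a group share one representative age, exactly as in the
reconstruction), non-normal FI% distributions, measurement error in the
published means/SDs themselves, and any sampling dependence between
endpoints measured on the same subjects.

## Numerical choices

* Logistic fitting: IRLS with deviance tolerance 1e-12, max 50 iterations,
  followed by Newton refinement until the score norm is below 1e-8 (the
  value is stored in the fit). Grouped-binomial and expanded-Bernoulli
  representations give identical estimates (tested to 1e-8).
* Complete separation and single-class outcomes are hard errors naming the
  endpoint — the bundled tables never separate, so separation signals
  malformed input. Silent penalisation would change the estimand.
* Gaussian fits use the closed-form simple-regression solution (the Monte
  Carlo engine performs 10,000 of them per endpoint); it is cross-checked
  against `stats::lm` to 1e-12 in the tests. A zero-residual fit has
  infinite Gaussian log-likelihood; the LR test defines the statistic as 0
  when both models fit perfectly.
* Reproducibility: every draw is governed by an `rng_spec` (seed + stream
  label), hashed to a Mersenne-Twister seed. The Monte Carlo engine uses
  one named sub-stream per (endpoint, iteration), so any endpoint — or any
  single iteration — can be regenerated in isolation, and identical specs
  are bit-identical. Draws never disturb the caller's RNG state.
* Interval separation in reports (`decline_report()`) uses strict
  inequality of bounds rounded to 3 decimals, the precision of the
  machine-readable outputs; human-readable output rounds to 2 decimals.

## Problem sizes used in validation

The packaged tests run the full 10,000-iteration simulation once for all
seven continuous endpoints (the same size as the default analysis) and use
reduced iteration counts (150–2,000) for structural and property checks,
where only ordering, determinism or coarse unbiasedness is at stake; the
stated Monte Carlo tolerances scale accordingly. The
`scripts/acceptance.R` entry point always runs the full 10,000 iterations.

## Known limitations

* The reconstruction inherits everything the aggregates hide: no
  within-group age resolution, no covariates, no between-study
  heterogeneity model (sources are pooled as published; no meta-analytic
  weighting).
* Decline rates for prevalence endpoints (percentage-point change in
  *prevalence* per year) and continuous endpoints (FI% units per year) are
  plotted on one %/year axis, as in the reference analysis; they are
  commensurable only in this loose descriptive sense.
* Two groups of the facet-degeneration and spondylolisthesis tables have
  assumed sample sizes (n = 100, flagged in `assumed_n`); their CIs are
  conditional on that assumption.
* Published summaries are themselves rounded (means/SDs to one decimal,
  prevalences to integer percent), which propagates as an irreducible
  half-ULP uncertainty into any reproduction of downstream results.
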