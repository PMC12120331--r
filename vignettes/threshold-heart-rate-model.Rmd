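---
title: "Modelling daily heart rate of a caged tuna: QC, aggregation and the threshold Poisson regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily heart rate of a caged tuna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotag)
```

## The problem

Archival heart-rate tags implanted in large fish log, every 10 minutes, a
short ECG burst (7.5 s at 200 Hz), peripheral temperature and tri-axial
acceleration. On-board firmware converts each ECG burst into an integer
heart rate (bpm) with a quality index (QI, 0 = excellent to 3 = poor) and
each acceleration burst into an average external acceleration (AvgEA,
milli-g). Over an 80-day cage deployment on an Atlantic bluefin tuna, the
scientific question is how daily heart rate responds to the seasonal
temperature decline and to feeding: the post-prandial rise in metabolic
rate (specific dynamic action) should raise heart rate after large
rations, but warm water may saturate cardiac scope and mask it. cardiotag
implements that analysis end to end — quality control, daily aggregation,
and Bayesian selection among nested Poisson regressions with a
temperature change-point — together with a synthetic-data generator that
stands in for the (undeposited) tag records so every stage is testable.

## The observation model

Let `HRm_t` be the daily median heart rate on day `t` (integer bpm), and
let the daily covariates be total feed `TF_t` (tons), median temperature
`TPm_t` (°C), temperature interquartile range `TPiq_t` (°C), and median
activity `ACm_t` (milli-g). The core model is an **identity-link** Poisson
regression

$$HRm_t \sim \mathrm{Poisson}(\mu_t), \qquad
  \mu_t = \alpha + \sum_i \beta_i X_{i,t},$$

optionally refined so that one covariate's coefficient switches at an
estimated threshold in a governing temperature variable:

$$\beta_{TF} = \begin{cases}\beta^{+}_{TF} & TPm_t > T_{thresh}\\
 \beta^{-}_{TF} & TPm_t \le T_{thresh}.\end{cases}$$

The identity link is deliberate: effects are additive in bpm, so an
intercept near 50 bpm is directly the expected heart rate at reference
conditions and slopes are bpm per ton or bpm per °C. The price is that
$\mu_t > 0$ is not automatic; the sampler enforces it by rejecting any
parameter state with a non-positive mean on the fitted data. Equality at
the threshold falls in the "below" branch (the strict inequalities leave
the boundary undefined; some convention is required and the measure-zero
choice is inconsequential).

Covariates are mean-centered before fitting (`center = TRUE`, switchable),
so $\alpha$ is the expected daily median heart rate at average deployment
conditions. The threshold comparison always uses the *uncentered*
governing covariate, keeping the estimated change-point in natural °C.

The candidate set (`enumerate_models()`) contains the 21 structures built
from all subsets of {TF, TPm, TPiq, ACm} with at most one threshold. A
label such as `TF:thresh` means the feeding coefficient switches at a
threshold in TPm; the temperature variables (`TPm:thresh`, `TPiq:thresh`)
threshold on themselves. For feeding-only structures (`alpha + TF:thresh`)
the switch is still governed by the TPm data column even though TPm has no
linear term — the temperature record exists regardless of which
coefficients enter the mean.

## Inference

`sample_posterior()` runs componentwise Gaussian random-walk Metropolis
(Metropolis-within-Gibbs). Defaults mirror the analysis protocol: 3
chains, 10,000 retained draws each after 10,000 burn-in. Step sizes adapt
during burn-in only (Robbins–Monro on the log step size, targeting 0.44
acceptance — the usual optimum for one-dimensional updates) and are frozen
before any draw is retained, so the retained chains are valid Markov
chains. Chains start from overdispersed draws around ordinary
least-squares estimates of the un-switched model; infeasible starting
points (any $\mu_t \le 0$) are redrawn with shrinking dispersion.

Priors are proper but diffuse: Normal(0, sd 100 bpm) on the intercept and
all slopes; the threshold is uniform between the 10% and 90% quantiles of
the governing covariate, further constrained so at least 3 observations
fall on each side. The constraint is what keeps the switched slopes
identifiable — a threshold beyond the data would make $\beta^{+}$ (or
$\beta^{-}$) a function of nothing.

Model comparison uses the deviance information criterion:
$\bar D$ is the posterior mean of $-2\log L$, $p_D = \bar D - D(\bar\theta)$
at the pooled posterior mean, and $DIC = \bar D + p_D$; five points is
treated as a meaningful difference, and ties are broken toward fewer
parameters. $p_D$ can go negative when the plug-in $\bar\theta$ is a poor
summary — typically here when the threshold posterior is bimodal and its
mean falls between modes. It is reported as-is with a warning rather than
clamped, since clamping would silently hide exactly the fits one should
inspect. Fit quality is additionally summarised by a classical
$R^2 = 1 - SSE/SST$ at posterior-mean predictions, which can be negative
for models worse than a constant. Convergence is checked with the
classical (non-split) Gelman–Rubin $\hat R$ from between/within-chain
variances, cutoff 1.1.

## Quality control and aggregation

Records with QI 2 or 3 are eliminated, as are heart rates above 120 bpm
or below 8 bpm. The bounds themselves are kept: 8 bpm equals
`theoretical_min_hr(7.5)` — the lowest rate for which one full beat-to-beat
interval fits the ECG window — so it is by definition a measurable value.
For reporting, each dropped record is charged to the first failing rule
(QI, then high HR, then low HR); the order affects tallies only, never
membership. Days are calendar days (UTC, no DST handling); the daily
median heart rate is rounded half-up to an integer because the Poisson
likelihood needs integer support, and `TPiq` uses linear-interpolation
(type-7) quantiles, configurable. Days with no surviving records are
omitted, not imputed.

## What the generator emulates — and what it does not

`deployment_config()` defaults encode the deployment conditions: 80 days
× 144 records, TPm declining linearly 27.5 → 19 °C with 0.3 °C daily
noise, within-day temperature spread growing (TPiq 0.4 → 1.5 °C) as the
season cools, activity drifting slightly upward (30 → 40 milli-g), daily
feed drawn right-skewed on [0, 20] tons so the full reported range is
attained over a deployment, with geometric fasting spells (start
probability 0.06/day, mean length 2 days), and QI corruption with
probability 0.15 — leaving ≈85% of records usable. Daily median heart
rates are Poisson draws from the best-supported structure at its reported
posterior means, which puts the deployment-level median of usable heart
rates at 50 ± 3 bpm.

Within a day, records scatter around the daily level by integer jitter
(discretised normal, SD 6 bpm) drawn as antithetic ± pairs, with QI
corruption striking whole pairs: the surviving jitter multiset is exactly
symmetric, so the post-QC daily median reproduces the generating daily
value. Jitter is truncated at 3.5 SD and at the distance to the 8–120 bpm
band, so clean records never leave the tag's output range. These are
constructions in service of testability, not claims about cardiac
physiology: real within-day heart rate has diel structure, autocorrelation
and feeding-time alignment that the generator does not model. Likewise the
pooled bimodal heart-rate histogram of real data emerges here only through
the seasonal trend, and no fish behaviour, cage hydrodynamics or ocean
temperature model is attempted. Passing tests therefore demonstrate that
the pipeline and estimator are correct and well calibrated *under the
model's own assumptions* — not that the model is adequate for any
particular real deployment.

The record count is a gap-free 11,520 (80 × 144); real deployments log
slightly fewer (gaps are unreported in the source data), and an optional
per-record dropout probability is available. Synthetic ECG bursts are
Gaussian-bump PQRST composites — only R-peak timing is meaningful — and
acceleration bursts place gravity along a fixed orientation with a
half-normal dynamic magnitude whose mean is the target activity level.

## Numerical choices

* **R-peak detection**: local maxima above 0.6 × the trace maximum,
  separated by ≥ 0.45 s (a ≈133 bpm refractory ceiling, just above the
  120 bpm QC bound). Deterministic; a flat trace is a no-signal error.
* **Heart rate** is 60 / mean R-R, rounded half-up, matching the tag's
  integer output. On a 7.5-s window the 8 bpm floor itself is attainable
  only with a beat on each window edge, which a finite sample grid cannot
  represent; recovery sweeps therefore start at 9 bpm and verify 8 bpm on
  a slightly longer window.
* **Activity**: EA = |‖a‖ − g| per sample (MSA-style absolute value,
  guaranteeing non-negativity; a signed variant is a flag), averaged over
  the burst.
* **Degenerate inputs**: an empty record stream has pass fraction 1 by
  convention; a zero-day deployment yields empty tables; constant HRm
  makes $R^2$ undefined (error, not NaN).
* **Reproducibility**: every generator and the sampler are seeded; the
  pipeline fans one global seed out to stages by fixed offsets, so stages
  are independently reproducible and a rerun is byte-identical.

## Problem sizes used in the tests

The test suite fits small models (≤ 2 parameters, ≤ 10 observations)
against dense-grid numerical integration — an oracle independent of the
sampler — requiring posterior means and SDs to agree within 2% of the
posterior SD. Parameter recovery runs ten 80-day replicates at the full
3 × (10,000 + 10,000) protocol; the 21-model selection study uses ten
replicates at reduced chain length (3 × 1,500 kept), where DIC
differences between structure families are an order of magnitude larger
than chain noise. These sizes were chosen so the whole suite illustrates
deployment-scale behaviour while remaining a routine desktop run.

## Known limitations

* The threshold posterior on 80 days of Poisson data is sometimes bimodal
  (a low-threshold mode where $\beta^{+}$ takes over most of the series);
  replicate-to-replicate variation of its posterior mean is then larger
  than any single fit's posterior SD, and $p_D$ can go negative. This is a
  property of change-point inference at this sample size, not of the
  sampler — duplicate-chain and long-run checks reproduce the same
  posterior.
* DIC is the only selection criterion, as in the source analysis; no
  WAIC/LOO, no gamma observation model, no multiple thresholds, and no
  autocorrelation structure in the daily series.
* Whether the original analysis centered covariates or rounded daily
  medians before fitting is unreported; both choices are explicit and
  switchable here, and they do not affect model ranking.
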