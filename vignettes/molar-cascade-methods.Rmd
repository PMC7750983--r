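---
title: "Methods: testing the inhibitory cascade on intraspecific molar samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing the inhibitory cascade on intraspecific molar samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmolar)
```

## The model

The inhibitory cascade treats the three lower molars as a developmental
module in which each tooth germ's final size is set by the running
balance of activator and inhibitor: relative size at position
$x \in \{1,2,3\}$ is $1 + [(a-i)/i](x-1)$, so with $s_1 = 1$ the row is
$(1,\ a/i,\ 2a/i - 1)$ and $M_3 = 2M_2 - M_1$. `icm_profile()` is this
rule; at $a/i \le 0.5$ the predicted $M_3$ is non-positive (third-molar
loss) and the function warns rather than errors, because that boundary
is biologically meaningful.

Because $M_3$ is a fixed linear combination of $M_1$ and $M_2$, the
model pins down not just means but the whole second-moment structure.
Six testable predictions follow, implemented in
`evaluate_icm_predictions()`:

1. the ratio-space regression of $M_3/M_1$ on $M_2/M_1$ explains
   substantial variance (`prediction_one_fit()`),
2. that regression is compatible with slope 2, intercept $-1$
   (`rma_regression()`),
3. $\mu(M_3/M_1) = 2\mu(M_2/M_1) - 1$ (`theoretical_m3_ratio()`),
4. $M_2$ is one third of the total row,
5. $\mathrm{var}$ of relative $M_3$ equals $\mathrm{var}$ of relative
   $M_1$,
6. $\sigma^2(M_3) = 4\sigma^2(M_2) + \sigma^2(M_1) - 4\sigma(M_1,M_2)$,
   $\sigma(M_1,M_3) = 2\sigma(M_1,M_2) - \sigma^2(M_1)$, and
   $\sigma(M_2,M_3) = 2\sigma^2(M_2) - \sigma(M_1,M_2)$
   (`theoretical_covariances()`).

The length-only variant (the molar module component) applies the same
predictions to mesiodistal crown lengths; the classic form uses the
rectangular crown-area estimate, length × width. Both metrics run in
parallel through the pipeline because they answer slightly different
biological questions (area is more exposed to body-size pleiotropy
through width).

## Estimation

### Measurement model and repeatability

Raw input is one row per measurement (specimen × tooth × dimension ×
replicate × observer). Percent repeatability is the among-specimen
variance fraction from a one-way ANOVA per tooth, averaged across
teeth, using the unbalanced-design estimator
$s^2_A = (MS_A - MS_W)/n_0$ with
$n_0 = (N - \sum n_i^2/N)/(a-1)$ and
$R = s^2_A/(s^2_A + MS_W)$, clipped to $(0, 1]$. Observers are pooled
into within-group error by default, so $R$ reflects total measurement
error within and between observers; this matches how $R$ is later used
to deflate posterior variances, which need the *total* error variance
removed. A two-way variant (`method = "two_way"`) that removes the
observer main effect is exposed for users whose observers are
systematically offset; it is not the default because the pooled form is
the conservative choice when the observer design is unknown. Area
repeatability pairs length and width within replicate × observer before
the ANOVA. Specimens contributing a single measurement are excluded
with a warning; if all are single, the estimator errors.

### The Bayesian posterior

`fit_size_posterior()` models the per-specimen $(M_1, M_2, M_3)$ sizes
as multivariate Gaussian with a flat prior on $\mu$ and an
inverse-Wishart prior on $\Sigma$ with scale $10^{-3} I_3$ and
$3.002$ degrees of freedom — diagonal scale (prior covariances zero),
degrees of freedom just above the dimension, i.e. close to
non-informative. Both full conditionals are conjugate, so the sampler
is a two-block Gibbs chain:
$\mu \mid \Sigma \sim N(\bar y, \Sigma/n)$ and
$\Sigma \mid \mu \sim IW(\nu_0 + n,\ V_0 + \sum_i (y_i-\mu)(y_i-\mu)')$.
The defaults (burn-in 500,000; every 1000th kept; 1000 draws) mirror
the long thinned chains conventional for non-conjugate mixed-model
samplers in this literature. A conjugate Gibbs chain mixes essentially
immediately — effective sample sizes at `burn_in = 2000, thin = 20` are
already at the nominal draw count, which the test suite checks with
`coda::effectiveSize()` — so tests and the acceptance script run with
burn-in 500–1000 and thin 2–5 and obtain the same posterior.

Two numerical consequences of the prior scale matter. First, exactly
collinear data (rows constructed with $M_3 = 2M_2 - M_1$) have a
singular sample covariance, but the posterior scale
$V_0 + \mathrm{SSE}$ stays positive definite, so the sampler runs; a
hard failure occurs only if the posterior scale itself fails its
Cholesky factorisation. Second, the $10^{-3}$ scale is small relative
to the sums of squares of any realistic sample measured in mm
(for 70 rodent molars, SSE entries are of order $0.3$ mm²), so the
prior's pull is negligible; users measuring in other units can pass
`iw_scale`.

Measurement error is removed by multiplying every *variance* draw by
the repeatability, leaving covariances and means untouched
(`adjust_measurement_error()`); the factor composes multiplicatively
and is recorded on the object.

### Observed/theoretical ratios, modes, HPDs

For each posterior draw the six observed quantities and their
theoretical counterparts are computed, and the posterior of each
observed/theoretical ratio is summarised by its kernel-density mode
(Gaussian kernel, Silverman's bandwidth, argmax on a 512-point grid)
and the 95% highest-posterior-density interval — the shortest
contiguous interval containing $\lceil 0.95 n \rceil$ sorted draws,
cross-checked in the tests against `coda::HPDinterval()`. A prediction
is *consistent* when its HPD contains 1.

Relative-size variances (prediction 5) are obtained per draw by the
delta method on $f(y) = y_i / (y_1+y_2+y_3)$ at that draw's
$(\mu, \Sigma)$: $\mathrm{var} \approx g'\Sigma g$ with
$g_j = (\delta_{ij} T - \mu_i)/T^2$. The alternative — simulating
individuals within each draw — adds Monte-Carlo noise without changing
the target at intraspecific CVs (a few percent), where the linearising
error is negligible; the tests verify the delta value against a
$2\times10^5$-sample Monte-Carlo estimate to 2%.

When a theoretical quantity is non-positive in more than 5% of draws,
its ratio posterior is not a meaningful quantity; the parameter is
reported with trimmed draws, flagged `unstable`, and its consistency
set to `NA` rather than being claimed in either direction. This is
deliberate: covariance denominators such as
$2\sigma(M_1,M_2) - \sigma^2(M_1)$ legitimately hover near zero in
weakly integrated samples, and an interval spanning $(-\infty,\infty)$
through a sign flip should not count as "consistent".

### RMA regression

The reduced major axis slope is $\mathrm{sign}(r)\, s_y/s_x$, the
intercept follows from the means, and the axis-swap identity
slope$(y{\sim}x)\cdot$slope$(x{\sim}y) = 1$ is enforced by
construction and tested. Confidence intervals are seeded bootstrap
percentile intervals over specimens (9,999 resamples by default);
association is tested by permuting $y$ against $x$ (999 permutations,
one-tailed on $|r|$, with the $+1$ adjustment so the smallest possible
p is $1/(n_{\mathrm{perm}}+1)$). Zero variance in either variable, or
an exactly zero correlation (sign-ambiguous slope), is an error.
Bootstrap resamples that collapse to zero variance are dropped as `NA`
rather than redrawn, keeping the resample count honest.

## The synthetic generator

`simulate_molar_rows()` generates the statistical structure the
pipeline consumes, not tooth development itself (no reaction–diffusion
fields, no agenesis). Three modes:

* **icm_exact** — $(M_1, M_2)$ bivariate Gaussian,
  $M_3 = 2M_2 - M_1 + \varepsilon$,
  $\varepsilon \sim N(0, \texttt{residual\_sd\_m3}^2)$. The cascade
  itself says nothing about intraspecific scatter off the plane; this
  Gaussian residual is our construction and is labelled as such.
* **activator_inhibitor** — per-specimen $a/i$ and $M_1$ draws pushed
  through the linear profile, so every specimen sits exactly on
  $r_{31} = 2 r_{21} - 1$ in ratio space.
* **mvn** — arbitrary mean vector and SPD covariance.

Defaults emulate the study conditions of an intraspecific sample of a
small myomorph rodent: 70 specimens; $M_1$ length 1.55 mm, SD 0.07 mm
(CV ≈ 4.5%, typical of rodent molar lengths); $a/i = 0.8$ (second
molars ≈ 80% of first molars, matching observed ratio medians around
0.80); widths 0.65 of lengths with 3% proportional noise so areas can
be derived from the same rows; two observers × three replicates with
noise calibrated so expected repeatability is 0.93. The $M_1$–$M_2$
correlation defaults to 0.9: within-row integration is strong, and the
cascade-implied $\mathrm{cov}(M_1, M_3) = 2\sigma_{12} - \sigma_1^2$
is positive only when $\rho > \sigma_1/(2\sigma_2)$ (= 0.625 at
$a/i = 0.8$). A generator intended to produce data that *satisfy* all
six predictions must sit well inside that region; at weaker
correlations the covariance ratio becomes indeterminate in exactly the
way the instability trim reports.

Sizes are simulated on the natural scale with rejection of negative
draws (counted; a warning fires above 10% rejection) rather than on a
log scale, keeping the Gaussian assumptions of the posterior model
exact; at the default mean/SD ratios (> 20) rejections essentially
never occur, so the truncation bias is nil. Replicate noise inverts
the repeatability estimator
($\sigma^2_W = \sigma^2_A (1-R)/R$ per tooth × dimension), so
`molar_repeatability()` recovers the target in expectation — the tests
check the round trip at $R = 0.93$ to ±0.03.

What the generator does **not** emulate: non-Gaussian size
distributions, allometric mean–variance scaling, missing teeth
(zero ratios are an input-data situation, handled and flagged by the
CV machinery but never generated), spatially structured sampling, or
observer bias with non-zero mean. Tests passing on synthetic data
therefore demonstrate the *machinery* is correct under the stated
model, not that real molar data satisfy that model.

## Resampling experiments

`reference_intervals()` computes the full-sample yardsticks: seeded
bootstrap percentile intervals (10,000 resamples) for the mean and SD
of each ratio. Three methods are available for the mean interval, and
the choice is recorded in the output's `method` column:

* `"bootstrap"` (default) — percentile interval of the resampled mean,
  a genuine CI of the mean (width $\sim 2 \cdot 1.96\, s/\sqrt{n}$,
  verified against normal theory in the tests);
* `"normal"` — the normal-theory version of the same;
* `"quantile"` — the inner 95% quantile interval of the per-specimen
  ratio distribution itself.

The distinction matters more than it looks. A subsample mean at
$N = 2$ has spread $\sigma/\sqrt{2}$, an order of magnitude wider than
the $n = 70$ mean CI, so against the *CI-of-the-mean* yardstick small
samples are never "adequate" (the default-method adequacy N on
study-condition synthetic data is ≈ 35). Judged against the
*ratio-distribution* yardstick — the scale on which a single complete
specimen, or a composite built from single teeth, is naturally scored —
adequacy for the mean is reached almost immediately (N = 2 on the same
synthetic data, via `adequate_n_for_mean_vs_ratio_distribution` in the
acceptance script). Published intraspecific results that report mean
adequacy at two specimens are interpretable only on the second scale,
which is why both are provided; the SD interval is always the
bootstrap percentile interval of the resampled SD.

`sample_size_simulation()` draws subsets *without* replacement at each
grid $N$ (10,000 pseudoreplicates by default), records the proportion
of subset means and SDs outside the reference intervals, and
`adequacy_threshold()` returns the first grid $N$ at ≤ 5% outside —
scanning in grid order even when the proportion sequence is
non-monotone (it logs the violation), because "smallest adequate N" is
the stated rule. At $N = n$ every subset is the full sample and both
proportions are exactly zero, which the tests use as an internal
consistency check.

`composite_simulation()` emulates the paleontological situation of
isolated teeth: per outer replicate, $N$ teeth per position drawn
independently with replacement (a composite cannot know specimen
identity), point estimate = ratio of per-position means (not mean of
ratios — the estimate a worker averaging isolated crowns actually
forms), and an inner loop (1000 by default) that resamples one tooth
per position to build a pseudosample SD. Defaults — grid 1..50, 1000
outer × 1000 inner — produce 50,000 composite datasets per run. Because
the independent draws destroy the within-specimen covariance between
positions, the pseudosample SD systematically overestimates the true
ratio SD whenever teeth covary positively; the `paired = TRUE`
validation mode keeps specimen identity through both loops and
recovers the variance structure, isolating independence (not
resampling per se) as the cause. At $N = 1$ the pseudosample is a
single row, its SD is exactly zero, and the SD proportion outside is
identically 1.

## Grouping diagnostics

CVs are $100\,s/\bar x$ with the $n-1$ SD. The sign test for
pooling-driven variance inflation is the one-sided exact binomial test
on how many subsample CVs fall below the pooled CV, ties dropped.
Pairwise Mann–Whitney U tests report the U of the first (row) group
under the rank-sum convention — so published asymmetric U tables can
be reproduced without guessing orientation — with exact enumeration
when both groups have $n \le 20$ and no ties, and the normal
approximation with tie correction otherwise; Bonferroni correction
multiplies by the number of pairs within each ratio separately, capped
at 1. `pooling_decision()` splits when any corrected p across the two
ratios falls below α, and raises the over-averaging flag when a pooled
ratio CV exceeds 15% — reported, never used to exclude data
automatically, since zero ratios from absent third molars legitimately
inflate CVs and are counted separately (an `exclude_zero` flag
reproduces the exclusion variant).

## Problem sizes and determinism

Every stochastic function takes a `seed` and restores the caller's RNG
state; the pipeline spawns per-stage seeds as
`seed + 1000 × stage rank`, so stages re-run in isolation reproduce
their outputs and identical configs produce identical bundles
(checked bit-for-bit in the tests). The test suite and acceptance
script run the simulations at reduced but statistically meaningful
sizes — e.g. 100 posterior fits of $n = 200$ for the six-prediction
consistency check, 500 simulated two-group datasets for the null split
rate, composite grids of 10 with 200–500 outer replicates — sizes
chosen so Monte-Carlo error is comfortably inside each check's margin.

## Known limitations

* The posterior assumes Gaussian sizes; strongly skewed or
  heteroscedastic samples violate it (a log-scale generator switch
  exists for robustness experiments, but the estimator itself stays on
  the natural scale).
* The delta-method relative-size variance degrades if intraspecific
  CVs are far larger than those seen in molar data.
* The instability trim reports, rather than resolves, weakly
  identified covariance ratios; samples with weak within-row
  integration will often return `NA` consistency for
  $\sigma(M_1, M_3)$.
* The ascending–descending generalisation of the cascade (nonlinear
  but monotone position effects) is intentionally out of scope: only
  the strict linear model is tested.
* Composite resampling assumes teeth are drawn from a single
  statistical population; time-averaged fossil accumulations add a
  source of variance the simulation does not model.
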