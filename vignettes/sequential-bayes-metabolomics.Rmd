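---
title: "Sequential Bayesian analysis of case-control metabolomics cohorts"
author: "bayesmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential Bayesian analysis of case-control metabolomics cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesmet)
```

## The problem

Univariate case-control metabolomics is usually analyzed one compound at a
time: regress the (preprocessed) abundance on a case/control indicator plus
clinical covariates, test the group coefficient, and correct across
compounds for multiple testing. A p-value alone cannot distinguish "no
effect" from "not enough data", and it discards whatever was learned by an
earlier cohort that measured the same compounds. `bayesmet` implements a
sequential Bayesian alternative: each compound gets a Bayesian linear
regression; the posterior for the group coefficient from one cohort becomes
the prior for the same compound in the next cohort; and decisions are read
off the posterior directly (credible intervals, probability of direction,
Savage-Dickey Bayes factors). A classical OLS +
Benjamini-Hochberg baseline and a chemical-class enrichment stage complete
the workflow, so frequentist and Bayesian readings of the same data sit
side by side.

## Model

For one compound with autoscaled log-abundance $y$ in a cohort of $n$
samples:

$$y_i = \beta_0 + \beta_p\, g_i + \mathbf{x}_i^\top \boldsymbol\gamma +
\varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2),$$

where $g_i \in \{0, 1\}$ is the case indicator, $\mathbf{x}_i$ holds the
encoded covariates (continuous covariates on their raw scale, categorical
covariates dummy-coded against the lexicographically first level), and
$\beta_p$ is the effect of interest on the autoscaled-log scale.

Default priors are weakly informative and data-scaled, in the style of
modern applied-regression defaults: each coefficient gets
$N(0,\, (2.5\,\mathrm{sd}(y)/\mathrm{sd}(x_j))^2)$, the intercept
$N(\bar y,\, (2.5\,\mathrm{sd}(y))^2)$, and the noise variance an
inverse-gamma$(2, \mathrm{sd}(y)^2)$ prior. The inverse-gamma (rather
than, say, an exponential prior on the noise SD) is a deliberate design
choice: it makes both Gibbs conditionals exact and admits a fully
conjugate normal-inverse-gamma variant that serves as an *analytic oracle*
for testing the sampler. Consequences of this choice are confined to the
noise nuisance; the acceptance checks are calibration-based rather than
draw-identical to any particular reference stack.

Three prior forms are supported:

* `independent` (default): fixed coefficient scales, inverse-gamma
  variance; semi-conjugate Gibbs.
* `nig`: coefficient scales multiplied by $\sigma$; fully conjugate, with
  a closed-form posterior (`analytic_posterior()`) whose $\beta_p$
  marginal is Student-t.
* `known`: $\sigma$ fixed; the coefficient posterior is exactly normal.
  Used for worked examples and the sequential-coherence checks.

## Sampling and decision statistics

`sample_posterior()` runs `n_chains` (default 4) chains of `n_iter`
(default 2000) iterations, discarding the first `n_burnin` (default 1000)
of each and pooling the rest, so the default yields 4000 pooled draws.
Chains beyond the first start from an overdispersed prior draw; split-R̂
is reported per compound and a warning is raised above 1.05 (a
convergence-screen convention, not a hard gate). Given a master seed,
per-compound seeds are derived by hashing the compound id, so analyzing a
subset of compounds never changes another compound's draws.

From the pooled draws, `summarize_posterior()` computes:

* the posterior median and the equal-tailed 95% credible interval
  (2.5/97.5 percentiles; equal-tailed rather than HPD, matching the
  "95% bounds" convention of the applied literature);
* **altered**: the interval excludes zero; direction is `up`/`down` by the
  sign of the median (negative = lower in cases);
* **pd**, the probability of direction: the fraction of draws on the
  majority sign (0.5 on an exact tie), the Bayesian analog of a two-sided
  p-value via $p = 2(1-\mathrm{pd})$, so pd = 0.975 corresponds to
  $p = 0.05$ — the same boundary at which the 95% interval starts
  excluding zero;
* **BF10** by the Savage-Dickey density ratio: prior density at
  $\beta_p = 0$ over posterior density at $0$, the latter estimated by a
  Gaussian kernel density with Silverman's bandwidth on the pooled draws
  (the analytic density replaces the KDE in `bf10_analytic()` when a
  conjugate form is active). Jeffreys bins cut BF10 at 1/10, 1/3, 3
  and 10.

A caveat worth stating plainly: a draw-based Savage-Dickey estimate is
only reliable where the draws actually cover the null value. When the
posterior sits several SD away from zero, the kernel bandwidth inflates
the estimated tail density and BF10 is biased; the package's own
consistency checks therefore place the null within 1.5 posterior SD,
where the KDE error stays well under 10%. Extremely large reported BFs
should be read as order-of-magnitude statements.

## Preprocessing

The chain is: presence filter, half-minimum imputation, natural-log
transform, autoscale — always within one cohort (no cross-cohort
normalization, since cohorts are analyzed sequentially, not jointly).

* **Presence filter** (`min_presence = 0.5`): a compound must be observed
  in at least half the samples; the boundary is inclusive. Zeros count as
  missing on load: in LC-MS intensities a zero is a non-detection, i.e.
  left-censoring at the limit of detection, not a measured concentration.
* **Half-minimum imputation**: each missing cell becomes half the
  compound's smallest observed intensity, on the raw scale, before the
  log transform. This is the standard left-censoring convention; the
  imputed value is by construction below every observed value.
* **Log + autoscale**: natural log, then per-compound standardization to
  mean 0, SD 1 (n−1 denominator). The log base is immaterial because
  autoscaling removes scale. Covariates are never autoscaled; age and BMI
  enter the model in their natural units, with the default prior scaling
  absorbing the unit differences.

Constant compounds fail autoscaling with an explicit error; they should
not survive upstream filters in real data.

## Posterior-to-prior chaining

`run_chain()` analyzes an ordered list of cohorts. Study 1 uses default
priors. For study $t+1$, compounds are matched to study $t$ (by full
27-character InChIKey by default — exact and case-sensitive, avoiding
stereoisomer collisions that first-block matching would invite — or by
name, or by a user-supplied mapping table for cross-assay
harmonization), and each matched compound's prior on $\beta_p$ becomes
$N(\text{posterior median},\ \text{posterior draw SD})$ from study $t$.
This normal summarization is a design choice: the sequential scheme needs
a parametric prior, the median matches the reporting convention, and for
the unimodal, nearly symmetric posteriors this model produces the normal
approximation is accurate.

Only $\beta_p$ is propagated. Intercept, covariate and noise priors reset
to each study's own defaults, because cohorts processed in different
laboratories share the biological effect of interest but not their error
structure. Two consequences are documented rather than hidden:

* $\beta_p$-only chaining is **order-sensitive** — chaining A→B is not
  B→A. The test suite asserts this non-equality instead of pretending
  exchangeability.
* Chaining propagates study-1 information into study-2 decisions; when
  study-1 effects are real but study-2's are null for the same compounds,
  the chained false-positive rate is inflated. The amplification study
  reports the realized false discovery rate alongside the gain.

A full-propagation path with known noise variance
(`chain_known_variance()`) passes the entire multivariate normal
posterior forward. Because normal precisions add, chaining over any
partition of one dataset then reproduces the pooled posterior exactly
(to numerical precision) — the coherence property the test suite checks
at 1e-10. Unmatched compounds silently fall back to default priors but
are counted in the chain manifest.

## Enrichment

`run_enrichment()` groups compounds by their annotated chemical class
(classes come from the annotation table; structure-based clustering is
out of scope), maps each compound's pd to the p-analog $2(1-\mathrm{pd})$,
and tests each class of at least 3 members with a one-sided, one-sample
Kolmogorov-Smirnov test against Uniform(0,1). One-sided because
enrichment means an excess of *small* p-analogs; a two-sided test would
also reward anti-enrichment. Classes labeled blank or "Unknown" are
excluded; classes below the size threshold are skipped with a log entry,
not an error. BH adjustment is applied across classes — the compound
level uses BH, so the class level follows the same convention. A class's
direction is `up`/`down` only when *every* member's posterior median
shares the sign (members are not filtered to altered ones first), else
`mixed`.

## The synthetic-cohort generator

`simulate_cohorts()` generates the structure the analysis assumes, with
known ground truth, so every stage is testable without external
downloads. Per compound, latent log-abundance is baseline +
$\delta \cdot$ group + covariate terms + $N(0, 1)$ noise; intensities are
exponentiated; cells below the compound's `lod_quantile` empirical
quantile are masked as missing. That makes missingness left-censored —
low-abundance, below-detection — not missing-at-random, which is exactly
the regime half-minimum imputation is meant for.

Defaults describe a desk-scale two-cohort case-control design: 50 cases
and 50 controls per study, 200 compounds all shared between studies, 80%
null, non-null standardized effects $\delta \sim N(0, 0.8^2)$ with
within-class correlation 0.7 across 10 chemical classes (so enrichment
has detectable signal; 0.7 is a package choice), age/sex/BMI covariates
with modest effects (0.01 per year, 0.2 for sex, 0.02 per BMI unit on
the log scale), and 10% censoring per compound — comfortably below the
~21% maximum missingness reported for real cohorts of this kind. Effects
are specified on the standardized log scale so ground truth is directly
comparable to $\beta_p$; note that the *realized* coefficient after
autoscaling is attenuated by the factor $\mathrm{sd}(\text{log-abundance})
> 1$ for non-null compounds, which the recovery metrics inherit.

What the generator does **not** emulate: instrument drift and batch
structure, correlated compounds within a sample beyond class-level effect
correlation, heavy-tailed or sample-specific noise, annotation errors,
and cohort-specific assay shifts. Passing the package's checks on this
generator therefore demonstrates statistical correctness of the
machinery, not robustness to every artifact of real LC-MS data.

## Validation studies and problem sizes

The package validates itself at these sizes (chosen as its own
desk-scale study conditions; `scripts/acceptance.R` recomputes them from
scratch):

* **Sampler vs oracle**: 100 random conjugate problems ($n \le 50$, up
  to 4 covariates); pooled-draw mean and variance of $\beta_p$ must agree
  with the closed form within 3 batch-means Monte-Carlo SEs in at least
  95% of problems.
* **Savage-Dickey**: 10 known-variance toys with the null within 1.5
  posterior SD; KDE BF10 within 10% of the analytic ratio, and BF10 = 1
  (±10%) in the no-data limit.
* **Sequential coherence**: full-propagation chaining over random 2-way
  partitions equals the pooled posterior to 1e-10; worked toy:
  $N(0,1)$ prior + two unit-information studies at 1 → $N(2/3, 1/3)$.
* **Null calibration**: 200 replicates of a 200-compound, 50-per-group
  global-null cohort at reduced MCMC (2 chains × 800, 300 burn-in,
  1000 pooled draws); CI-exclusion rate must sit in 5% ± 1%, and BH at
  FDR 0.10 must average fewer than one discovery per replicate.
* **Discovery amplification**: 50 replicate study pairs sharing true
  effects (80% null, effect SD 0.8, 50 per group) over a 632-compound
  shared panel — the size of compound panel two plasma LC-MS cohorts
  realistically share, and large enough that per-replicate altered
  counts are stable relative to their sampling noise; the chained
  study-2 altered count must be at least the unchained count in ≥90% of
  replicates, with the realized chained FDR reported rather than
  asserted.
* **Classical oracles**: BH against brute-force step-up enumeration on
  1000 random vectors; the KS statistic against a direct ECDF scan for
  all class sizes 3-12.
* **Determinism**: two identically seeded end-to-end runs produce
  byte-identical report bundles.

## Numerical choices and degenerate inputs

* Equal-tailed intervals use type-7 quantiles (R's default).
* pd ties (exactly half the draws positive) resolve to 0.5.
* The Gibbs sampler draws coefficients via a Cholesky factor of the
  conditional precision; a Cholesky failure (numerically non-PD
  precision) aborts with the chain and iteration named.
* Posteriors with all draws identical, compounds with zero observed
  values, zero-variance compounds or predictors, rank-deficient designs,
  duplicate matching keys, and empty result tables all raise explicit
  errors naming the offending entity.
* `summarize_posterior()` requires at least 100 pooled draws and warns
  below 1000, where Monte-Carlo error in the interval endpoints becomes
  visible.

## Known limitations

* The chained prior is a normal approximation of the source posterior;
  heavy-tailed or skewed posteriors (rare under this model) would be
  summarized too optimistically.
* $\beta_p$-only propagation is the deliberately simple scheme; a
  hierarchical joint model of all cohorts is a different estimator and
  out of scope.
* Subjects shared between consecutive cohorts are not deduplicated; if
  the same individuals appear in two chained studies, their information
  is counted twice.
* The KS enrichment treats member compounds as independent; correlated
  abundances within a class make the test anti-conservative.
* RefMet-style name harmonization is consumed as a ready-made mapping
  table; no online identifier resolution is performed.
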