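# bayesmet

Sequential Bayesian analysis of case-control metabolomics cohorts.

## What problem this solves, and for whom

Univariate metabolomics comparisons are usually run compound-by-compound
as covariate-adjusted regressions with p-values and a
Benjamini-Hochberg correction. That reading cannot distinguish "no
effect" from "underpowered", and it throws away everything an earlier
cohort learned about the same compounds. `bayesmet` is for metabolomics
and clinical-omics analysts who have two or more case-control cohorts
measuring overlapping compound panels (e.g. plasma metabolite studies of
the same disease) and want each study to *inform* the next instead of
being evaluated in isolation.

## The method

Per compound, with autoscaled log-abundance *y*, case indicator *g* and
encoded covariates **x**:

> y_i = β₀ + β_p·g_i + xᵢᵀγ + ε_i,  ε_i ~ N(0, σ²)

* **Priors**: weakly informative, data-scaled — each coefficient
  N(0, (2.5·sd(y)/sd(x_j))²), intercept N(ȳ, (2.5·sd(y))²), noise
  variance inverse-gamma(2, sd(y)²).
* **Posterior**: Gibbs sampling (4 chains × 2000 iterations, first 1000
  burn-in, compiled core), validated against an exact conjugate
  normal-inverse-gamma oracle.
* **Decisions**: a compound is *altered* when the equal-tailed 95%
  credible interval excludes zero (negative median = lower in cases);
  the probability of direction pd maps to a p-analog 2(1−pd); Bayes
  factors come from the Savage-Dickey density ratio at β_p = 0 with
  Jeffreys bins at 1/10, 1/3, 3, 10.
* **Chaining**: study t's per-compound posterior (median, draw SD)
  becomes study t+1's prior on β_p, matched by InChIKey; nuisance
  parameters reset per study. A known-variance full-propagation path
  reproduces the pooled posterior exactly when chaining over a partition.
* **Baseline**: the same design fitted by OLS with BH-FDR at 0.10.
* **Enrichment**: per chemical class, a one-sided Kolmogorov-Smirnov
  test of the members' p-analogs against Uniform(0,1), BH across classes.
* **Preprocessing**: ≥50% presence filter (inclusive), half-minimum
  imputation of left-censored cells (zeros count as missing), natural
  log, autoscale.
* **Synthetic cohorts**: a generator with known ground truth (left-
  censored missingness, class-correlated effects, covariates) makes the
  whole pipeline testable offline; deposited cohort tables can be read
  with `read_cohort()` when accession downloads are available.

## Worked example

Two synthetic 50-case/50-control cohorts sharing 200 compounds (80%
null), analyzed separately and then chained:

```r
library(bayesmet)

sim  <- simulate_cohorts(simulation_config(seed = 42))
proc <- lapply(sim$studies, function(s) preprocess(s)$data)
cfg  <- mcmc_config(seed = 42)

fr2 <- run_frequentist(proc[[2]])                 # classical baseline
un2 <- run_bayes(proc[[2]], config = cfg)         # study 2 on its own
ch  <- run_chain(proc, config = cfg)              # study 1 -> study 2
ch2 <- ch$results[[2]]

sum(fr2$significant); sum(un2$altered); sum(ch2$altered)
#> [1] 30
#> [1] 41
#> [1] 47

rec <- recovery_report(ch2, sim$truth)
round(c(cor = rec$correlation, fdr = rec$realized_fdr), 3)
#>   cor   fdr
#> 0.931 0.191

head(ch2[ch2$altered, c("compound_id", "posterior_median", "ci_low",
                        "ci_high", "pd", "bf10", "direction")], 2)
#>  compound_id posterior_median     ci_low    ci_high pd         bf10 direction
#>    CMP_S0004       -0.4974688 -0.7570326 -0.2458010  1 1.166816e+03      down
#>    CMP_S0008        0.9389703  0.7028869  1.1837837  1 1.647070e+127        up
```

Chaining study 1 into study 2 raises the altered count from 41 to 47 and
the posterior medians correlate at 0.93 with the generator's true
effects; the realized FDR of the chained calls (0.19) is reported rather
than hidden — the credible-interval rule does not control FDR, and
chained priors import study-1 information into study-2 decisions.
Class-level enrichment on the chained result:

```r
head(run_enrichment(ch2, proc[[2]]$compounds), 2)
#>  chem_class n_members   ks_stat ... p_adjusted direction
#>    CLASS_09        23 0.3263043 ... 0.04653648     mixed
#>    CLASS_01        27 0.2942963 ... 0.04653648     mixed
```

`run_all()` orchestrates every stage and writes a deterministic report
bundle (per-study TSV tables, plot-ready tables, JSON manifest).

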