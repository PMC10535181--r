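# Calibration and validation studies.  These run the package's own machinery
# on simulated data with known truth and report agreement rates; they back
# both the test suite and scripts/acceptance.R.

# Batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) draw sequence.
mcse_mean <- function(x) {
  n <- length(x)
  b <- max(2L, floor(sqrt(n)))
  nb <- n %/% b
  bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * b + 1):(i * b)]), 0)
  sd(bm) / sqrt(nb)
}

#' Sampler-versus-oracle agreement study
#'
#' Generates random small regression problems with conjugate
#' normal-inverse-gamma priors, runs the Gibbs sampler on each, and checks
#' that the pooled-draw mean and variance of the group coefficient agree
#' with the exact conjugate posterior within 3 batch-means Monte-Carlo
#' standard errors.
#'
#' @param n_problems number of random problems.
#' @param config MCMC settings per problem.
#' @param seed integer seed.
#' @param max_n,max_covariates problem-size caps.
#' @return list: \code{agreement_rate} (fraction of problems where both
#'   mean and variance agree), and the per-problem table.
#' @export
evaluate_sampler_agreement <- function(n_problems = 100,
                                       config = mcmc_config(4, 2000, 1000, 1),
                                       seed = 1, max_n = 50,
                                       max_covariates = 4) {
  set.seed(seed)
  rows <- vector("list", n_problems)
  for (i in seq_len(n_problems)) {
    n <- sample(15:max_n, 1)
    n_cov <- sample(0:(max_covariates - 1), 1)
    X <- cbind("(Intercept)" = 1, group = rep(0:1, length.out = n))
    if (n_cov > 0) {
      Z <- matrix(rnorm(n * n_cov), n)
      colnames(Z) <- paste0("z", seq_len(n_cov))
      X <- cbind(X, Z)
    }
    beta_true <- rnorm(ncol(X), 0, 0.7)
    y <- drop(X %*% beta_true) + rnorm(n, 0, runif(1, 0.5, 1.5))
    pr <- prior_spec(colnames(X), rnorm(ncol(X), 0, 0.3),
                     runif(ncol(X), 0.5, 2),
                     sigma_shape = 3, sigma_rate = 2, form = "nig")
    ap <- analytic_posterior(y, X, pr)
    cfg <- config; cfg$seed <- compound_seed(seed, paste0("problem", i))
    post <- sample_posterior(y, X, pr, cfg)
    d <- post$draws[, "group"]
    se_mean <- mcse_mean(d)
    se_var <- mcse_mean((d - mean(d))^2)
    mean_ok <- abs(mean(d) - ap$beta_p$mean) <= 3 * se_mean
    var_ok <- abs(var(d) - ap$beta_p$sd^2) <= 3 * se_var
    rows[[i]] <- data.frame(
      n = n, k = ncol(X),
      draw_mean = mean(d), analytic_mean = ap$beta_p$mean,
      draw_var = var(d), analytic_var = ap$beta_p$sd^2,
      mean_ok = mean_ok, var_ok = var_ok)
  }
  tab <- do.call(rbind, rows)
  list(agreement_rate = mean(tab$mean_ok & tab$var_ok), table = tab)
}

#' Savage-Dickey consistency study (known noise variance)
#'
#' Conjugate toys with the null value inside the bulk of the posterior
#' (the kernel density estimate is evaluated at zero; far in the tail the
#' Gaussian-kernel bandwidth inflates the density and any draw-based
#' Savage-Dickey estimate degrades). Compares the KDE Bayes factor with
#' the exact normal-density ratio, plus the no-data limit where BF10 = 1.
#'
#' @param n_toys number of toys.
#' @param seed integer seed.
#' @param config MCMC settings.
#' @return list: per-toy table (bf_kde, bf_analytic, rel_error),
#'   \code{max_rel_error}, and \code{no_data_bf10}.
#' @export
evaluate_savage_dickey <- function(n_toys = 10, seed = 1,
                                   config = mcmc_config(4, 6000, 1000, 1)) {
  set.seed(seed)
  rows <- vector("list", n_toys)
  for (i in seq_len(n_toys)) {
    n <- 30
    X <- cbind(group = rep(c(-1, 1), length.out = n))
    # place the posterior mean at z posterior-SDs from zero, |z| <= 1.5:
    # with known variance the posterior depends on the data only through
    # X'y, so y can be constructed to hit the target exactly
    z <- runif(1, -1.5, 1.5)
    post_sd <- 1 / sqrt(n + 1)           # prior N(0,1), sigma = 1
    bhat <- z * post_sd * (n + 1) / n
    y <- drop(X %*% bhat)
    pr <- prior_spec("group", 0, 1, sigma_known = 1, form = "known")
    cfg <- config; cfg$seed <- compound_seed(seed, paste0("sd_toy", i))
    post <- sample_posterior(y, X, pr, cfg)
    s <- summarize_posterior(post)
    bfa <- bf10_analytic(y, X, pr)
    rows[[i]] <- data.frame(bf_kde = s$bf10, bf_analytic = bfa,
                            rel_error = abs(s$bf10 / bfa - 1))
  }
  # no-data limit: a predictor that never varies carries no information on
  # beta_p, so posterior = prior and BF10 = 1
  X0 <- cbind(group = rep(0, 10), offset = rep(1, 10))
  y0 <- rnorm(10)
  pr0 <- prior_spec(c("group", "offset"), c(0.2, 0), c(0.8, 1),
                    sigma_known = 1, form = "known")
  cfg <- config; cfg$seed <- compound_seed(seed, "sd_nodata")
  post0 <- sample_posterior(y0, X0, pr0, cfg)
  s0 <- summarize_posterior(post0)
  tab <- do.call(rbind, rows)
  list(table = tab, max_rel_error = max(tab$rel_error),
       no_data_bf10 = s0$bf10)
}

#' Global-null calibration study
#'
#' Simulates all-null cohorts, runs the full preprocessing + Bayesian and
#' frequentist analyses, and reports the credible-interval exclusion rate
#' (nominal 5\%) and the count of Benjamini-Hochberg discoveries at the
#' given FDR (nominal ~0 under the global null).
#'
#' @param n_replicates simulation replicates.
#' @param n_compounds,n_per_group cohort shape per replicate.
#' @param config MCMC settings (reduced chains/iterations are adequate
#'   here; only the 95\% interval endpoints matter).
#' @param fdr_threshold BH threshold for the frequentist count.
#' @param seed integer seed.
#' @return list: \code{ci_exclusion_rate}, \code{mean_bh_discoveries},
#'   \code{max_bh_discoveries}, per-replicate table.
#' @export
evaluate_null_calibration <- function(n_replicates = 200, n_compounds = 200,
                                      n_per_group = 50,
                                      config = mcmc_config(2, 800, 300, 1),
                                      fdr_threshold = 0.10, seed = 1) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfgs <- simulation_config(n_studies = 1, n_cases = n_per_group,
                              n_controls = n_per_group,
                              n_compounds = n_compounds,
                              null_fraction = 1,
                              seed = compound_seed(seed, paste0("nullrep", r)))
    sim <- simulate_cohorts(cfgs)
    d <- preprocess(sim$studies[[1]])$data
    cfg <- config; cfg$seed <- compound_seed(seed, paste0("nullmcmc", r))
    bt <- run_bayes(d, config = cfg)
    fr <- run_frequentist(d, fdr_threshold = fdr_threshold)
    rows[[r]] <- data.frame(n_altered = sum(bt$altered),
                            n_compounds = nrow(bt),
                            n_bh = sum(fr$significant))
  }
  tab <- do.call(rbind, rows)
  list(ci_exclusion_rate = sum(tab$n_altered) / sum(tab$n_compounds),
       mean_bh_discoveries = mean(tab$n_bh),
       max_bh_discoveries = max(tab$n_bh),
       table = tab)
}

#' Discovery-amplification study
#'
#' Simulates pairs of cohorts sharing true effects, analyzes study 2 with
#' and without study 1's posteriors as priors, and reports how often
#' chaining finds at least as many altered compounds, along with the
#' realized false discovery rate of the chained calls.
#'
#' @param n_replicates simulation replicates.
#' @param n_compounds,n_per_group cohort shape.
#' @param null_fraction,effect_sd effect structure shared by both studies.
#' @param config MCMC settings.
#' @param seed integer seed.
#' @return list: \code{fraction_amplified}, mean altered counts,
#'   \code{chained_fdr}, \code{unchained_fdr}, per-replicate table.
#' @export
evaluate_amplification <- function(n_replicates = 50, n_compounds = 632,
                                   n_per_group = 50, null_fraction = 0.8,
                                   effect_sd = 0.8,
                                   config = mcmc_config(2, 800, 300, 1),
                                   seed = 1) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfgs <- simulation_config(n_studies = 2, n_cases = n_per_group,
                              n_controls = n_per_group,
                              n_compounds = n_compounds,
                              null_fraction = null_fraction,
                              effect_sd = effect_sd,
                              seed = compound_seed(seed, paste0("amprep", r)))
    sim <- simulate_cohorts(cfgs)
    d1 <- preprocess(sim$studies[[1]])$data
    d2 <- preprocess(sim$studies[[2]])$data
    cfg <- config; cfg$seed <- compound_seed(seed, paste0("ampmcmc", r))
    b1 <- run_bayes(d1, config = cfg)
    b2_un <- run_bayes(d2, config = cfg)
    priors <- chain_priors(b1, source_label = sim$studies[[1]]$provenance)
    b2_ch <- run_bayes(d2, priors = priors, config = cfg)
    nul <- sim$truth$effects$null[match(b2_ch$compound_id,
                                        sim$truth$effects$compound_id)]
    rows[[r]] <- data.frame(
      n_unchained = sum(b2_un$altered),
      n_chained = sum(b2_ch$altered),
      fp_chained = sum(b2_ch$altered & nul),
      fp_unchained = sum(b2_un$altered & nul))
  }
  tab <- do.call(rbind, rows)
  list(fraction_amplified = mean(tab$n_chained >= tab$n_unchained),
       mean_unchained = mean(tab$n_unchained),
       mean_chained = mean(tab$n_chained),
       chained_fdr = sum(tab$fp_chained) / max(1, sum(tab$n_chained)),
       unchained_fdr = sum(tab$fp_unchained) / max(1, sum(tab$n_unchained)),
       table = tab)
}
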