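# Per-compound Bayesian linear regression.
#
# Model: y = X beta + eps, eps ~ N(0, sigma2).  The coefficient of interest
# is the case/control indicator ("group"); everything else (intercept,
# covariates) is nuisance.  Priors come in three forms:
#   independent: beta_j ~ N(m_j, s_j^2), sigma2 ~ InvGamma(shape, rate).
#     The default, emulating weakly informative regression defaults with
#     scales tied to the data: 2.5 * sd(y) / sd(x_j).
#   nig: beta | sigma2 ~ N(m, sigma2 diag(s^2)) with sigma2 ~ InvGamma —
#     fully conjugate, admits the exact posterior used as a testing oracle.
#   known: sigma fixed; the posterior for beta is exactly normal.

#' Prior specification for one regression
#'
#' @param terms design column names the prior refers to.
#' @param location,scale numeric vectors (per term); all scales > 0.
#' @param sigma_shape,sigma_rate inverse-gamma prior on the noise variance
#'   (ignored when \code{form = "known"}).
#' @param sigma_known fixed noise SD for \code{form = "known"}.
#' @param form \code{"independent"} (default), \code{"nig"} or
#'   \code{"known"}; see the package vignette.
#' @param provenance \code{"default"} or \code{"chained-from:<study>"}.
#' @return object of class \code{prior_spec}.
#' @export
prior_spec <- function(terms, location, scale,
                       sigma_shape = 2, sigma_rate = 1, sigma_known = NA,
                       form = c("independent", "nig", "known"),
                       provenance = "default") {
  form <- match.arg(form)
  stopifnot(length(terms) == length(location),
            length(terms) == length(scale))
  if (any(scale <= 0) || anyNA(scale)) stop("all prior scales must be > 0")
  if (form == "known") {
    if (is.na(sigma_known) || sigma_known <= 0)
      stop("form = 'known' requires sigma_known > 0")
  } else if (sigma_shape <= 0 || sigma_rate <= 0) {
    stop("inverse-gamma shape and rate must be > 0")
  }
  structure(list(terms = as.character(terms),
                 location = as.numeric(location),
                 scale = as.numeric(scale),
                 sigma_shape = sigma_shape, sigma_rate = sigma_rate,
                 sigma_known = sigma_known,
                 form = form, provenance = provenance),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' Defaults: four chains of 2000 iterations, the first 1000 of each used as
#' burn-in, giving 4000 pooled draws.
#'
#' @param n_chains,n_iter,n_burnin chain count, iterations per chain,
#'   burn-in per chain (must be < n_iter).
#' @param seed master integer seed.
#' @return object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_chains = 4, n_iter = 2000, n_burnin = 1000,
                        seed = 1L) {
  if (n_chains < 1) stop("n_chains must be >= 1")
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter")
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Weakly informative default prior
#'
#' Coefficient priors are centered at zero with scale
#' \code{2.5 * sd(y) / sd(x)} per predictor column, the intercept at
#' \code{mean(y)} with scale \code{2.5 * sd(y)}, and the noise variance
#' gets an inverse-gamma(2, sd(y)^2) prior (prior mean sd(y)^2). These
#' scales adapt to the magnitudes of response and predictors without
#' dominating the likelihood.
#'
#' @param design model matrix (from \code{\link{encode_design}}).
#' @param y response vector.
#' @return a \code{prior_spec} of form \code{"independent"}.
#' @export
default_prior <- function(design, y) {
  if (ncol(design) < 1) stop("design needs at least one column")
  sdy <- sd(y)
  if (!is.finite(sdy) || sdy == 0) stop("response has zero variance")
  loc <- numeric(ncol(design))
  scl <- numeric(ncol(design))
  for (j in seq_len(ncol(design))) {
    x <- design[, j]
    if (all(x == 1)) {               # the intercept column
      loc[j] <- mean(y)
      scl[j] <- 2.5 * sdy
    } else {
      sdx <- sd(x)
      if (sdx == 0) stop("zero-variance predictor column: ",
                         colnames(design)[j])
      loc[j] <- 0
      scl[j] <- 2.5 * sdy / sdx
    }
  }
  prior_spec(colnames(design), loc, scl,
             sigma_shape = 2, sigma_rate = sdy^2,
             form = "independent", provenance = "default")
}

.align_prior <- function(prior, design) {
  idx <- match(colnames(design), prior$terms)
  if (anyNA(idx))
    stop("prior lacks terms: ",
         paste(colnames(design)[is.na(idx)], collapse = ", "))
  list(location = prior$location[idx], scale = prior$scale[idx])
}

#' Draw from the posterior by Gibbs sampling
#'
#' Alternates the exact conditional draws (coefficients | variance) ~
#' multivariate normal and (variance | coefficients) ~ inverse-gamma.
#' Deterministic given the seed in \code{config}.
#'
#' @param y response vector.
#' @param design model matrix; must be full rank.
#' @param prior a \code{prior_spec} covering every design column.
#' @param config an \code{mcmc_config}.
#' @param term coefficient of interest (default \code{"group"}).
#' @return object of class \code{posterior_draws}: pooled post-burn-in
#'   coefficient draws (\code{draws}), variance draws (\code{sigma2}),
#'   chain ids, and the prior/config used.
#' @export
sample_posterior <- function(y, design, prior = default_prior(design, y),
                             config = mcmc_config(), term = "group") {
  stopifnot(inherits(prior, "prior_spec"), inherits(config, "mcmc_config"))
  if (nrow(design) != length(y)) stop("y and design disagree in length")
  if (nrow(design) == 0) stop("no observations")
  al <- .align_prior(prior, design)
  set.seed(config$seed)
  res <- gibbs_lm_cpp(y, design, al$location, al$scale,
                      prior$sigma_shape, prior$sigma_rate,
                      prior$form,
                      ifelse(is.na(prior$sigma_known), 1.0,
                             prior$sigma_known),
                      config$n_chains, config$n_iter, config$n_burnin)
  colnames(res$beta) <- colnames(design)
  structure(list(draws = res$beta, sigma2 = res$sigma2,
                 chain = res$chain, prior = prior, config = config,
                 term = term),
            class = "posterior_draws")
}

#' Exact conjugate posterior
#'
#' Closed-form posterior for the conjugate prior forms; the oracle against
#' which the Gibbs sampler is validated.  For \code{form = "known"} the
#' posterior over coefficients is multivariate normal; for
#' \code{form = "nig"} it is normal-inverse-gamma, with a marginal
#' Student-t for each coefficient.
#'
#' @inheritParams sample_posterior
#' @return list with the joint posterior (\code{mean}, \code{cov} or
#'   scale factors) and \code{beta_p}: marginal mean/sd (plus t location,
#'   scale, df in the nig case) for the term of interest.
#' @export
analytic_posterior <- function(y, design, prior, term = "group") {
  stopifnot(inherits(prior, "prior_spec"))
  if (length(y) == 0) stop("no observations")
  if (nrow(design) != length(y)) stop("y and design disagree in length")
  al <- .align_prior(prior, design)
  p_idx <- match(term, colnames(design))
  if (is.na(p_idx)) stop("term '", term, "' not in design")
  P0 <- diag(1 / al$scale^2, ncol(design))
  XtX <- crossprod(design)
  Xty <- crossprod(design, y)

  if (prior$form == "known") {
    s2 <- prior$sigma_known^2
    Prec <- XtX / s2 + P0
    cov <- solve(Prec)
    mean_ <- cov %*% (Xty / s2 + P0 %*% al$location)
    return(list(form = "known", mean = drop(mean_), cov = cov,
                beta_p = list(mean = mean_[p_idx],
                              sd = sqrt(cov[p_idx, p_idx]))))
  }
  if (prior$form == "nig") {
    n <- length(y)
    A <- XtX + P0
    Ainv <- solve(A)
    mu <- drop(Ainv %*% (Xty + P0 %*% al$location))
    shape_post <- prior$sigma_shape + n / 2
    rate_post <- prior$sigma_rate +
      0.5 * (sum(y^2) + drop(t(al$location) %*% P0 %*% al$location) -
             drop(t(mu) %*% A %*% mu))
    if (rate_post <= 0) stop("degenerate conjugate update (rate <= 0)")
    df <- 2 * shape_post
    t_scale <- sqrt(rate_post / shape_post * Ainv[p_idx, p_idx])
    return(list(form = "nig", mean = mu, Ainv = Ainv,
                shape_post = shape_post, rate_post = rate_post,
                beta_p = list(mean = mu[p_idx],
                              sd = t_scale * sqrt(df / (df - 2)),
                              location = mu[p_idx], scale = t_scale,
                              df = df)))
  }
  stop("unsupported prior form for the analytic path: '", prior$form,
       "' (conjugate forms are 'known' and 'nig')")
}

# Gaussian kernel density at a point, Silverman bandwidth.
.kde_at <- function(draws, at = 0) {
  bw <- bw.nrd0(draws)
  if (bw <= 0) stop("degenerate draws: zero kernel bandwidth")
  mean(dnorm(at, mean = draws, sd = bw))
}

# Marginal prior density of the term of interest at a point.
.prior_density_at <- function(prior, term, at = 0) {
  i <- match(term, prior$terms)
  if (is.na(i)) stop("term '", term, "' not in prior")
  if (prior$form == "nig") {
    s0 <- prior$scale[i] * sqrt(prior$sigma_rate / prior$sigma_shape)
    dt((at - prior$location[i]) / s0, df = 2 * prior$sigma_shape) / s0
  } else {
    dnorm(at, prior$location[i], prior$scale[i])
  }
}

#' Split-chain R-hat
#'
#' Potential scale reduction factor computed on chains split in half.
#'
#' @param x draw vector, \code{chain} parallel integer chain ids.
#' @param chain integer chain membership per draw.
#' @return R-hat, or NA when chains are too short.
#' @export
split_rhat <- function(x, chain) {
  pieces <- list()
  for (c_ in unique(chain)) {
    xs <- x[chain == c_]
    h <- length(xs) %/% 2
    if (h < 2) return(NA_real_)
    pieces <- c(pieces, list(xs[1:h], xs[(h + 1):(2 * h)]))
  }
  m <- length(pieces); n <- length(pieces[[1]])
  means <- vapply(pieces, mean, 0)
  vars <- vapply(pieces, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Jeffreys evidence category of a Bayes factor
#'
#' Bins BF10 at the conventional boundaries 1/10, 1/3, 3 and 10.
#'
#' @param bf10 numeric vector of Bayes factors (alternative vs null).
#' @return factor with levels strong_null, moderate_null, anecdotal,
#'   moderate_alt, strong_alt.
#' @export
jeffreys_bin <- function(bf10) {
  cut(bf10, breaks = c(0, 1 / 10, 1 / 3, 3, 10, Inf),
      labels = c("strong_null", "moderate_null", "anecdotal",
                 "moderate_alt", "strong_alt"),
      include.lowest = TRUE)
}

#' Summarize posterior draws into decision statistics
#'
#' Equal-tailed 95\% credible interval, posterior median, probability of
#' direction (share of draws on the majority sign; 0.5 on an exact tie),
#' Savage-Dickey Bayes factor (prior density at zero over posterior
#' density at zero, the latter from a Gaussian kernel density on the
#' pooled draws), Jeffreys bin, and the altered/direction call: a compound
#' is altered when the 95\% interval excludes zero, with a negative median
#' indicating downregulation in cases.
#'
#' @param post a \code{posterior_draws} object.
#' @param min_draws hard minimum pooled-draw count (a warning is issued
#'   below 1000, where Monte-Carlo error starts to matter).
#' @return one-row data.frame: posterior_median, ci_low, ci_high, post_sd,
#'   pd, bf10, jeffreys_bin, altered, direction, rhat, n_draws.
#' @export
summarize_posterior <- function(post, min_draws = 100) {
  s <- .summarize_core(post, min_draws)
  as.data.frame(s, stringsAsFactors = FALSE)
}

.summarize_core <- function(post, min_draws = 100) {
  stopifnot(inherits(post, "posterior_draws"))
  x <- post$draws[, post$term]
  n <- length(x)
  if (n < min_draws) stop("need at least ", min_draws, " pooled draws, got ", n)
  if (n < 1000)
    warning("only ", n, " pooled draws; summaries carry visible Monte-Carlo error")
  if (all(x == x[1])) stop("degenerate posterior: all draws identical")
  qs <- unname(quantile(x, c(0.025, 0.5, 0.975), type = 7, names = FALSE))
  med <- qs[2]
  pd <- max(mean(x > 0), mean(x < 0), 0.5)
  bf10 <- .prior_density_at(post$prior, post$term, 0) / .kde_at(x, 0)
  altered <- qs[1] > 0 || qs[3] < 0
  direction <- if (!altered) "none" else if (med > 0) "up" else "down"
  rhat <- if (length(unique(post$chain)) >= 2)
    split_rhat(x, post$chain) else NA_real_
  if (is.finite(rhat) && rhat > 1.05)
    warning(sprintf("split R-hat %.3f exceeds 1.05; chains may not have mixed",
                    rhat))
  list(posterior_median = med, ci_low = qs[1], ci_high = qs[3],
       post_sd = sd(x), pd = pd, bf10 = bf10,
       jeffreys_bin = as.character(jeffreys_bin(bf10)),
       altered = altered, direction = direction,
       rhat = rhat, n_draws = n)
}

#' Analytic Savage-Dickey Bayes factor
#'
#' Exact density ratio for the conjugate prior forms: prior over posterior
#' density of the group coefficient at zero.
#'
#' @param y,design,prior,term as in \code{\link{analytic_posterior}}.
#' @return BF10 as a number.
#' @export
bf10_analytic <- function(y, design, prior, term = "group") {
  ap <- analytic_posterior(y, design, prior, term)
  post_dens <- if (ap$form == "known") {
    dnorm(0, ap$beta_p$mean, ap$beta_p$sd)
  } else {
    dt((0 - ap$beta_p$location) / ap$beta_p$scale, df = ap$beta_p$df) /
      ap$beta_p$scale
  }
  .prior_density_at(prior, term, 0) / post_dens
}

# Deterministic per-compound seed: polynomial byte hash folded with the
# master seed, kept below 2^31 - 1 so it is a valid R integer seed.
compound_seed <- function(master_seed, compound_id) {
  h <- 0
  for (b in utf8ToInt(compound_id)) h <- (h * 31 + b) %% 2147483647
  as.integer((h * 7919 + (master_seed %% 2147483647)) %% 2147483647)
}

#' Bayesian differential-abundance analysis of one cohort
#'
#' Runs the Gibbs sampler per compound with either the supplied prior on
#' the group coefficient or the weakly informative default, and collects
#' decision statistics. Per-compound seeds are derived deterministically
#' from the master seed and the compound id, so subsetting compounds never
#' changes another compound's draws.
#'
#' @param d a preprocessed (autoscaled) \code{cohort_dataset}.
#' @param priors optional data.frame \code{compound_id}, \code{location},
#'   \code{scale} (and optionally \code{provenance}) overriding the group
#'   coefficient prior for listed compounds; all other coefficients keep
#'   their study-specific defaults.
#' @param config an \code{mcmc_config}; \code{config$seed} is the master
#'   seed.
#' @param covariates covariate columns to adjust for; \code{NULL} = all.
#' @return data.frame, one row per compound: compound_id, the
#'   \code{\link{summarize_posterior}} columns, and prior_provenance.
#' @export
run_bayes <- function(d, priors = NULL, config = mcmc_config(),
                      covariates = NULL) {
  stopifnot(inherits(d, "cohort_dataset"))
  if (d$stage != "autoscaled")
    stop("dataset must be preprocessed (autoscaled) first")
  if (ncol(d$abundance) == 0) stop("no compounds to analyze")
  X <- encode_design(d$samples, covariates)
  ids <- colnames(d$abundance)
  if (!is.null(priors)) {
    priors <- as.data.frame(priors)
    stopifnot(all(c("compound_id", "location", "scale") %in% names(priors)))
    if (anyDuplicated(priors$compound_id))
      stop("duplicate compound_id in priors table")
  }
  rows <- vector("list", length(ids))
  provs <- character(length(ids))
  for (j in seq_along(ids)) {
    y <- d$abundance[, j]
    pr <- default_prior(X, y)
    prov <- "default"
    if (!is.null(priors)) {
      i <- match(ids[j], priors$compound_id)
      if (!is.na(i)) {
        gi <- match("group", pr$terms)
        pr$location[gi] <- priors$location[i]
        pr$scale[gi] <- priors$scale[i]
        prov <- if ("provenance" %in% names(priors))
          priors$provenance[i] else "chained"
        pr$provenance <- prov
      }
    }
    cfg <- config
    cfg$seed <- compound_seed(config$seed, ids[j])
    post <- sample_posterior(y, X, pr, cfg)
    rows[[j]] <- withCallingHandlers(
      .summarize_core(post),
      warning = function(w) invokeRestart("muffleWarning"))
    provs[j] <- prov
  }
  grab <- function(field) vapply(rows, `[[`, rows[[1]][[field]], field)
  data.frame(compound_id = ids,
             posterior_median = grab("posterior_median"),
             ci_low = grab("ci_low"), ci_high = grab("ci_high"),
             post_sd = grab("post_sd"), pd = grab("pd"),
             bf10 = grab("bf10"), jeffreys_bin = grab("jeffreys_bin"),
             altered = grab("altered"), direction = grab("direction"),
             rhat = grab("rhat"), n_draws = grab("n_draws"),
             prior_provenance = provs,
             stringsAsFactors = FALSE, row.names = NULL)
}
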