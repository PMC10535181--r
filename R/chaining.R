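# Posterior -> prior chaining across cohorts.
#
# The sequential scheme passes only the group coefficient forward: the next
# study's prior on beta_p is normal(source posterior median, source draw SD),
# while intercept, covariate and noise priors are reset to that study's own
# defaults (cohorts processed in different laboratories share the effect of
# interest, not their error structure).  A full-propagation analytic path
# with known noise variance is provided as well; with it, chaining over a
# partition of one dataset reproduces the all-at-once posterior exactly.

#' Turn a study's posterior table into priors for the next study
#'
#' @param source a \code{\link{run_bayes}} result table (needs
#'   \code{compound_id}, \code{posterior_median}, \code{post_sd}).
#' @param pairs optional data.frame \code{compound_id_a} (ids in
#'   \code{source}), \code{compound_id_b} (ids in the target study), as
#'   produced by \code{\link{match_compounds}}; \code{NULL} maps compounds
#'   to themselves.
#' @param source_label study name recorded in the provenance.
#' @return priors data.frame (\code{compound_id} on the target side,
#'   \code{location}, \code{scale}, \code{provenance}) suitable for
#'   \code{run_bayes(priors = ...)}. Target compounds absent from it fall
#'   back to default priors.
#' @export
chain_priors <- function(source, pairs = NULL, source_label = "source") {
  stopifnot(all(c("compound_id", "posterior_median", "post_sd") %in%
                  names(source)))
  if (is.null(pairs))
    pairs <- data.frame(compound_id_a = source$compound_id,
                        compound_id_b = source$compound_id,
                        stringsAsFactors = FALSE)
  idx <- match(pairs$compound_id_a, source$compound_id)
  if (anyNA(idx))
    stop("source posterior table lacks compound(s): ",
         paste(pairs$compound_id_a[is.na(idx)], collapse = ", "))
  sds <- source$post_sd[idx]
  if (any(sds <= 0))
    stop("degenerate source posterior (SD 0) for: ",
         paste(pairs$compound_id_a[sds <= 0], collapse = ", "))
  data.frame(compound_id = pairs$compound_id_b,
             location = source$posterior_median[idx],
             scale = sds,
             provenance = paste0("chained-from:", source_label),
             stringsAsFactors = FALSE)
}

#' Sequential Bayesian analysis across an ordered list of cohorts
#'
#' Study 1 is analyzed with default weakly informative priors; each later
#' study uses the previous study's per-compound posterior (median, draw SD)
#' as the prior on the group coefficient, matched by the chosen key.
#' Unmatched compounds silently receive default priors but are counted in
#' the manifest.
#'
#' @param studies ordered list of \code{cohort_dataset}s (raw datasets are
#'   preprocessed with defaults first).
#' @param config an \code{mcmc_config}; the same master seed drives every
#'   study (per-compound seeds differ by compound id).
#' @param covariates covariate columns to adjust for; \code{NULL} = all.
#' @param key matching key passed to \code{\link{match_compounds}}.
#' @param mappings for \code{key = "mapping"}: list of mapping tables, one
#'   per consecutive study pair.
#' @return list with \code{results} (one posterior table per study) and
#'   \code{manifest} (per-study compound counts and prior provenance).
#' @export
run_chain <- function(studies, config = mcmc_config(), covariates = NULL,
                      key = "inchikey", mappings = NULL) {
  if (length(studies) < 2) stop("need at least two studies to chain")
  for (i in seq_along(studies)) {
    stopifnot(inherits(studies[[i]], "cohort_dataset"))
    if (nrow(studies[[i]]$abundance) == 0)
      stop("study ", i, " has zero samples")
    if (studies[[i]]$stage != "autoscaled")
      studies[[i]] <- preprocess(studies[[i]])$data
  }
  n_st <- length(studies)
  results <- vector("list", n_st)
  manifest <- vector("list", n_st)
  results[[1]] <- run_bayes(studies[[1]], NULL, config, covariates)
  manifest[[1]] <- list(study = studies[[1]]$provenance,
                        n_compounds = nrow(results[[1]]),
                        n_chained = 0L,
                        n_default = nrow(results[[1]]))
  for (t in 2:n_st) {
    mp <- if (key == "mapping") mappings[[t - 1]] else NULL
    mt <- match_compounds(studies[[t - 1]], studies[[t]], key = key,
                          mapping = mp)
    if (nrow(mt$pairs) == 0)
      stop("no overlapping compounds between studies ", t - 1, " and ", t)
    priors <- chain_priors(results[[t - 1]], mt$pairs,
                           source_label = studies[[t - 1]]$provenance)
    results[[t]] <- run_bayes(studies[[t]], priors, config, covariates)
    manifest[[t]] <- list(study = studies[[t]]$provenance,
                          n_compounds = nrow(results[[t]]),
                          n_chained = sum(results[[t]]$prior_provenance !=
                                            "default"),
                          n_default = sum(results[[t]]$prior_provenance ==
                                            "default"))
  }
  list(results = results, manifest = manifest)
}

#' Exact posterior update with known noise variance
#'
#' Multivariate normal prior on all coefficients, fixed noise SD: the
#' posterior is normal with precision prior-precision + X'X / sigma^2.
#'
#' @param y,X data for one study.
#' @param prior_mean,prior_cov multivariate normal prior over coefficients.
#' @param sigma known noise SD.
#' @return list \code{mean}, \code{cov}.
#' @export
posterior_known <- function(y, X, prior_mean, prior_cov, sigma) {
  if (length(y) == 0) stop("study has zero samples")
  P0 <- solve(prior_cov)
  Prec <- P0 + crossprod(X) / sigma^2
  cov <- solve(Prec)
  mean_ <- cov %*% (P0 %*% prior_mean + crossprod(X, y) / sigma^2)
  list(mean = drop(mean_), cov = (cov + t(cov)) / 2)
}

#' Full-propagation analytic chaining (known noise variance)
#'
#' Folds \code{\link{posterior_known}} over an ordered list of studies,
#' passing the entire multivariate normal posterior forward as the next
#' prior. Because normal precisions add, chaining over any partition of
#' one dataset reproduces the pooled single-fit posterior exactly.
#'
#' @param studies list of \code{list(y =, X =)} per study.
#' @param prior_mean,prior_cov initial prior.
#' @param sigma known noise SD (shared across studies).
#' @return list with \code{posteriors} (one mean/cov per study) and
#'   \code{final}.
#' @export
chain_known_variance <- function(studies, prior_mean, prior_cov, sigma) {
  if (!length(studies)) stop("no studies supplied")
  out <- vector("list", length(studies))
  cur_mean <- prior_mean; cur_cov <- prior_cov
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    p <- posterior_known(st$y, st$X, cur_mean, cur_cov, sigma)
    out[[i]] <- p
    cur_mean <- p$mean; cur_cov <- p$cov
  }
  list(posteriors = out, final = out[[length(out)]])
}
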