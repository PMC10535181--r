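# Synthetic multi-cohort case-control metabolomics generator with known
# ground truth.  Emulates the structure the analysis assumes: per-compound
# log-normal intensities, a standardized group effect for a minority of
# compounds, covariate effects, chemical classes with correlated effects
# (so enrichment has signal), and left-censored missingness at a
# per-compound limit-of-detection quantile -- not missing-at-random.

.default_covariates <- function() {
  list(
    age = list(type = "continuous", mean = 50, sd = 10, effect = 0.01),
    sex = list(type = "categorical", levels = c("F", "M"), effect = 0.2),
    bmi = list(type = "continuous", mean = 26, sd = 4, effect = 0.02)
  )
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale two-cohort ME/CFS-like design: 50 cases
#' and 50 controls per study, 200 compounds all shared across studies, 80\%
#' of compounds null, non-null standardized effects drawn from
#' N(0, 0.8^2) with within-class correlation 0.7, age/sex/BMI covariates,
#' and 10\% left-censoring per compound.
#'
#' @param n_studies number of cohorts.
#' @param n_cases,n_controls per-study group sizes.
#' @param n_compounds compounds per study.
#' @param shared_compound_fraction fraction of compounds common to all
#'   studies (shared compounds carry identical true effects).
#' @param null_fraction probability a compound has a zero group effect.
#' @param effect_sd SD (tau) of non-null standardized effects.
#' @param covariates covariate specification (see
#'   \code{bayesmet:::.default_covariates}); \code{NULL} disables
#'   covariates entirely.
#' @param lod_quantile per-compound left-censoring quantile in [0, 0.3];
#'   0 disables missingness.
#' @param n_classes number of chemical classes.
#' @param class_rho within-class correlation of non-null effects.
#' @param noise_sd residual SD on the log scale.
#' @param baseline_mean,baseline_sd distribution of per-compound baseline
#'   log-intensities.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_studies = 2, n_cases = 50, n_controls = 50,
                              n_compounds = 200,
                              shared_compound_fraction = 1.0,
                              null_fraction = 0.8, effect_sd = 0.8,
                              covariates = .default_covariates(),
                              lod_quantile = 0.1,
                              n_classes = 10, class_rho = 0.7,
                              noise_sd = 1,
                              baseline_mean = 15, baseline_sd = 1.5,
                              seed = 1L) {
  if (null_fraction < 0 || null_fraction > 1)
    stop("null_fraction must lie in [0, 1]")
  if (lod_quantile < 0 || lod_quantile > 0.3)
    stop("lod_quantile must lie in [0, 0.3]")
  if (shared_compound_fraction < 0 || shared_compound_fraction > 1)
    stop("shared_compound_fraction must lie in [0, 1]")
  if (min(n_studies, n_cases, n_controls, n_compounds, n_classes) < 1)
    stop("all counts must be positive")
  if (class_rho < 0 || class_rho > 1) stop("class_rho must lie in [0, 1]")
  structure(as.list(environment()), class = "simulation_config")
}

.random_inchikey <- function(n) {
  blk <- function(k) vapply(seq_len(n), function(i)
    paste(sample(LETTERS, k, replace = TRUE), collapse = ""), "")
  paste0(blk(14), "-", blk(10), "-", blk(1))
}

.draw_effects <- function(n, cfg, class_id) {
  null_flag <- runif(n) < cfg$null_fraction
  u_class <- rnorm(cfg$n_classes)
  delta <- ifelse(null_flag, 0,
                  cfg$effect_sd * (sqrt(cfg$class_rho) * u_class[class_id] +
                                   sqrt(1 - cfg$class_rho) * rnorm(n)))
  list(delta = delta, null = null_flag)
}

#' Simulate multi-cohort case-control metabolomics data
#'
#' Per compound, latent log-abundance = baseline + delta * group +
#' covariate terms + N(0, noise_sd); intensities are the exponentials.
#' Cells whose latent value falls below the compound's
#' \code{lod_quantile} empirical quantile are masked as missing
#' (left-censoring). Compounds shared across studies carry identical true
#' effects; each study also gets its own unshared compounds when
#' \code{shared_compound_fraction < 1}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{studies} (raw \code{cohort_dataset}s) and
#'   \code{truth}: per-compound effects table (compound_id, delta, null,
#'   chem_class), covariate effect sizes, per-study latent log matrices,
#'   and the config.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)

  n_shared <- round(cfg$shared_compound_fraction * cfg$n_compounds)
  n_own <- cfg$n_compounds - n_shared

  make_annotation <- function(ids) {
    class_id <- sample.int(cfg$n_classes, length(ids), replace = TRUE)
    data.frame(compound_id = ids,
               name = paste0("compound ", ids),
               inchikey = .random_inchikey(length(ids)),
               chem_class = sprintf("CLASS_%02d", class_id),
               stringsAsFactors = FALSE,
               row.names = NULL)
  }

  shared_ids <- sprintf("CMP_S%04d", seq_len(n_shared))
  shared_ann <- make_annotation(shared_ids)
  shared_cls <- as.integer(sub("CLASS_", "", shared_ann$chem_class))
  shared_eff <- .draw_effects(n_shared, cfg, shared_cls)
  shared_base <- rnorm(n_shared, cfg$baseline_mean, cfg$baseline_sd)

  cov_spec <- cfg$covariates
  truth_rows <- list(data.frame(compound_id = shared_ids,
                                delta = shared_eff$delta,
                                null = shared_eff$null,
                                chem_class = shared_ann$chem_class,
                                stringsAsFactors = FALSE))
  studies <- vector("list", cfg$n_studies)
  latents <- vector("list", cfg$n_studies)

  for (s in seq_len(cfg$n_studies)) {
    ann <- shared_ann
    delta <- shared_eff$delta
    base <- shared_base
    if (n_own > 0) {
      own_ids <- sprintf("CMP_%d_%04d", s, seq_len(n_own))
      own_ann <- make_annotation(own_ids)
      own_cls <- as.integer(sub("CLASS_", "", own_ann$chem_class))
      own_eff <- .draw_effects(n_own, cfg, own_cls)
      ann <- rbind(ann, own_ann)
      delta <- c(delta, own_eff$delta)
      base <- c(base, rnorm(n_own, cfg$baseline_mean, cfg$baseline_sd))
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(compound_id = own_ids, delta = own_eff$delta,
                   null = own_eff$null, chem_class = own_ann$chem_class,
                   stringsAsFactors = FALSE)
    }
    n <- cfg$n_cases + cfg$n_controls
    smp <- data.frame(sample_id = sprintf("ST%d_S%03d", s, seq_len(n)),
                      group = c(rep(1, cfg$n_cases), rep(0, cfg$n_controls)),
                      stringsAsFactors = FALSE)
    cov_term <- numeric(n)
    if (length(cov_spec)) {
      for (cv in names(cov_spec)) {
        spec <- cov_spec[[cv]]
        if (spec$type == "continuous") {
          val <- rnorm(n, spec$mean, spec$sd)
          smp[[cv]] <- val
          cov_term <- cov_term + spec$effect * (val - spec$mean)
        } else {
          val <- sample(spec$levels, n, replace = TRUE)
          smp[[cv]] <- val
          cov_term <- cov_term + spec$effect * (val != spec$levels[1])
        }
      }
    }
    m <- length(delta)
    noise <- matrix(rnorm(n * m, 0, cfg$noise_sd), n, m)
    z <- outer(rep(1, n), base) + outer(smp$group, delta) +
      matrix(cov_term, n, m) + noise
    dimnames(z) <- list(smp$sample_id, ann$compound_id)
    intensity <- exp(z)
    if (cfg$lod_quantile > 0) {
      for (j in seq_len(m)) {
        thr <- quantile(z[, j], cfg$lod_quantile, type = 7)
        intensity[z[, j] < thr, j] <- NA
      }
    }
    studies[[s]] <- cohort_dataset(intensity, smp, ann,
                                   provenance = paste0("synthetic_study_", s))
    latents[[s]] <- z
  }

  truth <- list(effects = do.call(rbind, truth_rows),
                covariate_effects =
                  if (length(cov_spec))
                    vapply(cov_spec, function(x) x$effect, 0) else numeric(0),
                latent = latents,
                config = cfg)
  list(studies = studies, truth = truth)
}

#' Parameter-recovery metrics against simulation ground truth
#'
#' Compares a Bayesian result table with the generator's true effects:
#' bias, RMSE and correlation of posterior medians versus the true
#' standardized effects (medians are attenuated relative to delta because
#' autoscaling divides by the total, effect-inflated, SD), plus
#' sensitivity and realized false discovery rate of the altered rule and
#' the mean pd among null compounds.
#'
#' @param results \code{\link{run_bayes}} table.
#' @param truth the \code{truth} element of \code{\link{simulate_cohorts}}.
#' @return list of metrics plus the merged per-compound table.
#' @export
recovery_report <- function(results, truth) {
  eff <- truth$effects
  idx <- match(results$compound_id, eff$compound_id)
  if (anyNA(idx))
    stop("truth lacks compound(s): ",
         paste(results$compound_id[is.na(idx)], collapse = ", "))
  delta <- eff$delta[idx]
  nul <- eff$null[idx]
  med <- results$posterior_median
  altered <- results$altered
  n_alt <- sum(altered)
  list(bias = mean(med - delta),
       rmse = sqrt(mean((med - delta)^2)),
       correlation = if (sd(delta) > 0) cor(med, delta) else NA_real_,
       sensitivity = if (any(!nul)) mean(altered[!nul]) else NA_real_,
       false_positive_rate = if (any(nul)) mean(altered[nul]) else NA_real_,
       realized_fdr = if (n_alt > 0) sum(altered & nul) / n_alt else NA_real_,
       mean_pd_null = if (any(nul)) mean(results$pd[nul]) else NA_real_,
       table = cbind(results,
                     data.frame(true_delta = delta, true_null = nul)))
}

#' @importFrom stats cor
NULL
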